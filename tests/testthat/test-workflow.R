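# Build a demo study on disk: PRE tables for two effector states, the
# four-sample sPRE design, and a snapshot trajectory, all synthetic.
demo_study <- function(dir, seed = 17) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  probes <- list(V197 = c(10, 0, 0), V20 = c(16, 4, 0), L12 = c(40, 10, 0),
                 I237 = c(38, -8, 4), I225 = c(6, -3, 1))
  trp_model <- loop_ensemble_model(
    members = rbind(c(0, 0, 0), c(42, 0, 0)), weights = c(0.08, 0.92),
    probe_sites = probes, noise_sigma = 500
  )
  tyr_model <- loop_ensemble_model(
    members = rbind(c(0, 0, 0), c(42, 0, 0)), weights = c(0.01, 0.99),
    probe_sites = probes, noise_sigma = 500
  )
  trp <- generate_pre_tables(trp_model, seed = seed, state = "trp")
  tyr <- generate_pre_tables(tyr_model, seed = seed + 1, state = "tyr")

  psi <- c(V197 = 1.2, V20 = 0.8, L12 = -1.5, I237 = 0.6, I225 = -0.3)
  spre <- list(
    wt_low = generate_spre_tables(surface_charge_model(psi), seed = seed + 2,
                                  construct = "WT", pH = 6.5),
    wt_high = generate_spre_tables(surface_charge_model(psi * 0.9), seed = seed + 3,
                                   construct = "WT", pH = 7.5),
    mut_low = generate_spre_tables(surface_charge_model(psi * 1.8), seed = seed + 4,
                                   construct = "D215A", pH = 6.5),
    mut_high = generate_spre_tables(surface_charge_model(psi * 0.5), seed = seed + 5,
                                    construct = "D215A", pH = 7.5)
  )
  snaps <- generate_snapshots(n_frames = 80, f_close_inter = 0.1, seed = seed + 6)

  paths <- list()
  samples <- list()
  put <- function(name, tab) {
    p <- file.path(dir, paste0(name, ".tsv"))
    write_peak_table(tab, p)
    meta <- table_meta(tab)
    samples[[name]] <<- list(
      path = p,
      meta = list(state = meta$state, magnetic = meta$magnetic,
                  cosolute = meta$cosolute, pH = meta$pH,
                  nacl_mM = meta$nacl_mM, protein_conc_uM = meta$protein_conc_uM,
                  construct = meta$construct, covalent_label = meta$covalent_label)
    )
  }
  put("trp_dia", trp$dia); put("trp_para", trp$para)
  put("tyr_dia", tyr$dia); put("tyr_para", tyr$para)
  for (nm in names(spre)) {
    put(paste0(nm, "_dia"), spre[[nm]]$dia)
    put(paste0(nm, "_plus"), spre[[nm]]$plus)
    put(paste0(nm, "_minus"), spre[[nm]]$minus)
  }
  snap_path <- file.path(dir, "snapshots.tsv")
  write_snapshots(snaps$snapshots, snap_path)
  samples$traj <- list(path = snap_path, snapshots = TRUE)

  phi_stage <- function(id, nm) {
    list(id = id, type = "phi", dia = paste0(nm, "_dia"),
         plus = paste0(nm, "_plus"), minus = paste0(nm, "_minus"))
  }
  config <- list(
    seed = seed,
    out_dir = file.path(dir, "out"),
    samples = samples,
    stages = list(
      list(id = "pre_trp", type = "pre", dia = "trp_dia", para = "trp_para"),
      list(id = "pre_tyr", type = "pre", dia = "tyr_dia", para = "tyr_para"),
      list(id = "delta_trp_tyr", type = "delta_i", a = "pre_trp", b = "pre_tyr"),
      phi_stage("phi_wt_low", "wt_low"),
      phi_stage("phi_wt_high", "wt_high"),
      phi_stage("phi_mut_low", "mut_low"),
      phi_stage("phi_mut_high", "mut_high"),
      list(id = "significance", type = "significance",
           wt_low = "phi_wt_low", wt_high = "phi_wt_high",
           mut_low = "phi_mut_low", mut_high = "phi_mut_high"),
      list(id = "census", type = "distances", snapshots = "traj")
    )
  )
  list(config = config, truth = list(trp = trp$truth, tyr = tyr$truth,
                                     snaps = snaps$truth))
}

test_that("the demo pipeline runs end to end and recovers planted signal", {
  dir <- withr::local_tempdir()
  study <- demo_study(dir)
  run <- suppressMessages(run_pipeline(study$config))

  outs <- file.path(dir, "out", paste0(names(run$results), ".tsv"))
  expect_true(all(file.exists(outs)))
  expect_true(file.exists(file.path(dir, "out", "run_log.json")))

  # activator-state PREs exceed inhibitor-state PREs at the planted site
  d <- run$results$delta_trp_tyr
  expect_gt(d$delta_i[d$residue_index == 197], 0)
  # the distance census recovers the planted close fraction regime
  f <- close_fraction(run$results$census, "inter")
  expect_lt(abs(f - 0.1), 2 * sqrt(0.1 * 0.9 / 160))
  expect_gt(min_class_distance(run$results$census, "intra"), 25)

  # the run log echoes every effective stage parameter (no silent defaults)
  log <- jsonlite::read_json(file.path(dir, "out", "run_log.json"))
  expect_equal(log$stages$pre_trp$parameters$bleach_snr_threshold, 3)
  expect_equal(log$stages$significance$parameters$ddphi_threshold, 0.4)
  expect_equal(log$stages$census$parameters$low, 5)
  expect_equal(log$seed, study$config$seed)
})

test_that("reruns are no-ops with byte-identical tabular outputs", {
  dir <- withr::local_tempdir()
  study <- demo_study(dir)
  run1 <- suppressMessages(run_pipeline(study$config))
  md5_1 <- tools::md5sum(file.path(dir, "out", paste0(names(run1$results), ".tsv")))
  run2 <- suppressMessages(run_pipeline(study$config))
  md5_2 <- tools::md5sum(file.path(dir, "out", paste0(names(run2$results), ".tsv")))
  expect_identical(md5_1, md5_2)
  log <- jsonlite::read_json(file.path(dir, "out", "run_log.json"))
  expect_true(all(vapply(log$stages, function(s) isTRUE(s$skipped), logical(1))))
})

test_that("a missing sample path fails validation before any stage runs", {
  dir <- withr::local_tempdir()
  study <- demo_study(dir)
  study$config$samples$trp_dia$path <- file.path(dir, "absent.tsv")
  study$config$out_dir <- file.path(dir, "out2")
  expect_error(run_pipeline(study$config), class = "premap_validation_error")
  expect_false(dir.exists(file.path(dir, "out2")))
})

test_that("stage failures name the failing stage", {
  dir <- withr::local_tempdir()
  study <- demo_study(dir)
  study$config$out_dir <- file.path(dir, "out3")
  study$config$stages <- list(
    list(id = "bad_delta", type = "delta_i", a = "pre_missing", b = "pre_tyr")
  )
  expect_error(run_pipeline(study$config), "bad_delta")
})
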