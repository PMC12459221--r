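# In-memory snapshot tibbles go through the TSV path so tests exercise
# the same reader users rely on.
snap_from_df <- function(df, ...) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  readr::write_tsv(df, path, progress = FALSE)
  read_snapshots(path, ...)
}

dimer_frame <- function(frame, loop_a, site_a, loop_b, site_b) {
  tibble::tibble(
    frame = frame,
    chain = c("A", "A", "B", "B"),
    resno = c(220L, 197L, 220L, 197L),
    resname = c("SER", "VAL", "SER", "VAL"),
    atom = c("HG1", "HG11", "HG1", "HG11"),
    x = c(loop_a[1], site_a[1], loop_b[1], site_b[1]),
    y = c(loop_a[2], site_a[2], loop_b[2], site_b[2]),
    z = c(loop_a[3], site_a[3], loop_b[3], site_b[3])
  )
}

test_that("distances reproduce simple geometry across all four pairings", {
  snaps <- snap_from_df(dimer_frame(
    1L, loop_a = c(0, 0, 0), site_a = c(3, 4, 0),
    loop_b = c(0, 0, 0), site_b = c(10, 0, 0)
  ))
  census <- distance_series(snaps)
  expect_equal(nrow(census), 4L)
  expect_equal(census$class, c("intra", "inter", "inter", "intra"))
  aa <- census$distance_A[census$loop_chain == "A" & census$site_chain == "A"]
  expect_equal(aa, 5)  # 3-4-5 triangle
  # loop B is coincident with loop A here: B->A distance is also 5,
  # and B->B is 10; A->B equals |loopA - siteB| = 10
  expect_equal(census$distance_A[census$loop_chain == "B" & census$site_chain == "B"], 10)
  coincident <- snap_from_df(dimer_frame(
    1L, c(1, 2, 3), c(1, 2, 3), c(5, 5, 5), c(9, 9, 9)
  ))
  expect_equal(min_class_distance(distance_series(coincident), "intra"), 0)
})

test_that("the census is bit-identical to an independent brute-force recount", {
  gen <- generate_snapshots(n_frames = 20, f_close_inter = 0.3, seed = 9)
  census <- distance_series(gen$snapshots)
  brute <- brute_force_census(tibble::as_tibble(gen$snapshots))
  brute <- brute[order(brute$frame, brute$loop_chain, brute$site_chain), ]
  expect_identical(census$distance_A, brute$distance_A)
  expect_identical(census$class, brute$class)
  expect_equal(
    min_class_distance(census, "intra"),
    min(brute$distance_A[brute$class == "intra"])
  )
  expect_equal(
    min_class_distance(census, "inter"),
    min(brute$distance_A[brute$class == "inter"])
  )
})

test_that("distances are invariant under a rigid transform of each frame", {
  gen <- generate_snapshots(n_frames = 5, f_close_inter = 0.5, seed = 33)
  atoms <- tibble::as_tibble(gen$snapshots)
  theta <- 1.1
  rot <- matrix(c(cos(theta), -sin(theta), 0,
                  sin(theta), cos(theta), 0,
                  0, 0, 1), 3, byrow = TRUE)
  xyz <- as.matrix(atoms[, c("x", "y", "z")]) %*% rot
  moved <- atoms
  moved$x <- xyz[, 1] + 17.3; moved$y <- xyz[, 2] - 8.1; moved$z <- xyz[, 3] + 2.2
  c0 <- distance_series(gen$snapshots)
  c1 <- distance_series(snap_from_df(moved))
  expect_equal(c1$distance_A, c0$distance_A, tolerance = 1e-9)
})

test_that("close fractions are exact counts over the half-open window", {
  far <- lapply(1:10, function(f) dimer_frame(
    f, c(0, 0, 0), c(30, 0, 0), c(0, 40, 0), c(30, 40, 0)
  ))
  snaps <- snap_from_df(dplyr::bind_rows(far))
  census <- distance_series(snaps)
  expect_equal(close_fraction(census, "inter"), 0)
  expect_error(close_fraction(census, "both"))

  # 48 of 600 inter records at 10 A, the rest at 40 A -> exactly 0.08
  frames <- lapply(1:300, function(f) {
    d <- if (f <= 24) 10 else 40   # both inter legs of a frame sit at d
    dimer_frame(f,
                loop_a = c(0, 0, 0), site_a = c(30, 0, 0),
                loop_b = c(30, d, 0), site_b = c(0, d, 0))
  })
  census2 <- distance_series(snap_from_df(dplyr::bind_rows(frames)))
  inter_d <- census2$distance_A[census2$class == "inter"]
  expect_equal(length(inter_d), 600L)
  expect_equal(sum(inter_d >= 5 & inter_d < 15), 48L)
  expect_equal(close_fraction(census2, "inter"), 0.08)

  # boundary: a distance exactly at the upper edge is excluded (half-open)
  edge <- distance_series(snap_from_df(dimer_frame(
    1L, c(0, 0, 0), c(40, 0, 0), c(80, 0, 0), c(15, 0, 0)
  )))
  # inter legs: loopA->siteB = 15 (at the edge), loopB->siteA = 40
  expect_equal(close_fraction(edge, "inter"), 0)
  expect_equal(close_fraction(edge, "inter", low = 5, high = 15 + 1e-9), 0.5)
})

test_that("histogram counts sum to the records per class", {
  gen <- generate_snapshots(n_frames = 50, f_close_inter = 0.2, seed = 5)
  census <- distance_series(gen$snapshots)
  h <- distance_histogram(census, binwidth = 2)
  for (cl in c("inter", "intra")) {
    expect_equal(sum(h$count[h$class == cl]), sum(census$class == cl))
  }
})

test_that("multi-model PDB snapshots are parsed, with per-frame rejection", {
  gen <- generate_snapshots(n_frames = 3, f_close_inter = 0.5, seed = 2)
  pdb_path <- withr::local_tempfile(fileext = ".pdb")
  write_snapshots(gen$snapshots, pdb_path)
  snaps <- read_snapshots(pdb_path)
  expect_equal(length(unique(snaps$frame)), 3L)
  census <- distance_series(snaps)
  reference <- distance_series(gen$snapshots)
  expect_equal(census$distance_A, reference$distance_A, tolerance = 5e-3)

  # a frame missing the active-site proton is rejected and reported
  atoms <- tibble::as_tibble(gen$snapshots)
  broken <- atoms[!(atoms$frame == 2L & atoms$atom == "HG11" & atoms$chain == "B"), ]
  expect_warning(
    kept <- snap_from_df(broken),
    "missing required atoms"
  )
  expect_equal(sort(unique(kept$frame)), c(1L, 3L))
  expect_equal(attr(kept, "rejected_frames")$frame, 2L)

  # a monomer-only file cannot support the inter/intra census
  mono <- atoms[atoms$chain == "A", ]
  expect_error(snap_from_df(mono), class = "premap_validation_error")
})

test_that("heavy-atom snapshots fall back to the parent heavy atom with a warning", {
  gen <- generate_snapshots(n_frames = 2, f_close_inter = 0, seed = 4)
  atoms <- tibble::as_tibble(gen$snapshots)
  atoms$atom[atoms$atom == "HG1"] <- "OG"
  atoms$atom[atoms$atom == "HG11"] <- "CG1"
  snaps <- snap_from_df(atoms)
  expect_warning(census <- distance_series(snaps), "fell back")
  used <- attr(census, "atoms_used")
  expect_identical(used$atom[used$role == "loop"], "OG")
  expect_identical(used$atom[used$role == "site"], "CG1")
  expect_equal(nrow(census), 8L)
})

test_that("ambiguous selectors raise a selection error listing matches", {
  atoms <- dimer_frame(1L, c(0, 0, 0), c(3, 4, 0), c(9, 9, 9), c(12, 13, 9))
  dup <- atoms[atoms$atom == "HG11", ]
  dup$x <- dup$x + 0.5
  both <- dplyr::bind_rows(atoms, dup)
  snaps <- snap_from_df(both, require = NULL)
  expect_error(distance_series(snaps), class = "premap_selection_error")
})
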