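# CSV dialect, validation and lossless round trips.

make_minimal_files <- function(dir, drop_control = FALSE) {
  layout <- data.frame(
    well_id = c("A1", "A2"),
    role = c("sample", "buffer_control"),
    probe_id = "p1",
    protein_id = c("prot", ""),
    protein_pmol = c("5", ""),
    competitor_id = "", competitor_excess = "",
    buffer_id = "buf",
    replicate_group = c("grp", "ctrl"),
    control_group = c(if (drop_control) "" else "ctrl", ""),
    volume_ul = "100",
    stringsAsFactors = FALSE
  )
  pts <- expand.grid(point_row = 1:2, point_col = 1:2)
  scans <- do.call(rbind, lapply(c("A1", "A2"), function(w) {
    do.call(rbind, lapply(1:2, function(k) {
      data.frame(well_id = w, scan_index = k, pts,
                 intensity = 100 + k, stringsAsFactors = FALSE)
    }))
  }))
  write.csv(layout, file.path(dir, "layout.csv"), row.names = FALSE)
  write.csv(scans, file.path(dir, "scans.csv"), row.names = FALSE)
  dir
}

test_that("a minimal two-well plate reads and validates", {
  d <- withr::local_tempdir()
  make_minimal_files(d)
  plate <- read_plate(file.path(d, "layout.csv"), file.path(d, "scans.csv"))
  expect_s3_class(plate, "pife_plate")
  expect_equal(nrow(plate$layout), 2)
  expect_equal(sort(unique(plate$scans$scan_index)), 1:2)
  expect_true(is.na(plate$layout$protein_id[2])) # empty string -> NA
})

test_that("validation names the specific violation", {
  d <- withr::local_tempdir()
  make_minimal_files(d, drop_control = TRUE)
  expect_error(
    read_plate(file.path(d, "layout.csv"), file.path(d, "scans.csv")),
    "unpaired sample group"
  )

  d2 <- withr::local_tempdir()
  make_minimal_files(d2)
  sc <- read.csv(file.path(d2, "scans.csv"), colClasses = "character")
  sc$intensity[3] <- "oops"
  write.csv(sc, file.path(d2, "scans.csv"), row.names = FALSE)
  expect_error(
    read_plate(file.path(d2, "layout.csv"), file.path(d2, "scans.csv")),
    "non-numeric intensity in scans row\\(s\\): 3"
  )

  d3 <- withr::local_tempdir()
  make_minimal_files(d3)
  sc <- read.csv(file.path(d3, "scans.csv"), colClasses = "character")
  sc$well_id[1:8] <- "Z9"
  write.csv(sc, file.path(d3, "scans.csv"), row.names = FALSE)
  expect_error(
    read_plate(file.path(d3, "layout.csv"), file.path(d3, "scans.csv")),
    "Z9"
  )
})

test_that("validation rejects single-field corruptions of a valid plate", {
  plate <- random_plate(n_groups = 2, grid_size = 3, seed = 11)
  expect_true(validate_plate(plate))

  mutations <- list(
    function(p) { p$layout$well_id[2] <- p$layout$well_id[1]; p },
    function(p) { p$layout$role[1] <- "mystery"; p },
    function(p) { p$layout$volume_ul[1] <- -5; p },
    function(p) { p$layout$protein_pmol[1] <- -1; p },
    function(p) { p$layout$control_group[1] <- "ghost"; p },
    function(p) { p$scans$intensity[10] <- -2; p },
    function(p) { p$scans$intensity[4] <- Inf; p },
    function(p) { p$scans$scan_index[1] <- 7L; p },
    function(p) { p$scans <- p$scans[-1, ]; p }, # incomplete grid
    function(p) { # a well losing its reference scan
      p$scans <- p$scans[!(p$scans$well_id == p$scans$well_id[1] &
                             p$scans$scan_index == 1), ]; p
    }
  )
  for (mutate in mutations) {
    expect_error(validate_plate(mutate(plate)))
  }
})

test_that("write/read round trip is lossless and bit-identical", {
  for (seed in c(3, 17, 29)) {
    plate <- random_plate(seed = seed)
    d <- withr::local_tempdir()
    paths <- write_plate(plate, d)
    back <- read_plate(paths["layout"], paths["scans"])
    rownames(plate$scans) <- rownames(back$scans) <- NULL
    rownames(plate$layout) <- rownames(back$layout) <- NULL
    expect_identical(back$layout, plate$layout)
    expect_identical(back$scans, plate$scans)
  }
})

test_that("absent third scans serialize as absent rows, not zeros", {
  cond <- data.frame(replicate_group = c("g", "ctrl"),
                     role = c("sample", "buffer_control"),
                     control_group = c("ctrl", NA), theta = c(0.4, NA),
                     stringsAsFactors = FALSE)
  plate <- simulate_plate(cond, sim_config(grid_size = 2, n_scans = 2),
                          seed = 5, n_replicates = 1)
  d <- withr::local_tempdir()
  paths <- write_plate(plate, d)
  sc <- read.csv(paths["scans"])
  expect_false(any(sc$scan_index == 3))
  expect_false(any(sc$intensity == 0))
})

test_that("a full 96-well three-scan plate has the expected cell count", {
  cond <- data.frame(
    replicate_group = c(sprintf("g%d", 1:31), "ctrl"),
    role = c(rep("sample", 31), "buffer_control"),
    control_group = c(rep("ctrl", 31), NA),
    theta = c(rep(0.3, 31), NA), stringsAsFactors = FALSE
  )
  plate <- simulate_plate(cond, sim_config(n_scans = 3), seed = 2,
                          n_replicates = 3)
  expect_equal(nrow(plate$layout), 96)
  expect_equal(nrow(plate$scans), 96 * 3 * 10 * 10) # 28,800 intensity cells
})
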