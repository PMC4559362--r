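test_that("grid size is the product of level counts", {
  expect_equal(nrow(generate_grid()), 625)
  two <- grid_spec(IFNg = c(0, 1), IL12 = c(0, 1), IL6 = c(0, 1),
                   TGFb = c(0, 1))
  expect_equal(nrow(generate_grid(two)), 16)
  withr::with_seed(5, {
    for (rep in 1:5) {
      counts <- sample(1:4, 4, replace = TRUE)
      levels <- lapply(counts, function(k) sort(runif(k)))
      spec <- grid_spec(IFNg = levels[[1]], IL12 = levels[[2]],
                        IL6 = levels[[3]], TGFb = levels[[4]])
      expect_equal(nrow(generate_grid(spec)), prod(counts))
    }
  })
})

test_that("grid rows follow lexicographic order over the inputs", {
  g <- generate_grid()
  expect_equal(unname(unlist(g[1, ])), c(0, 0, 0, 0))
  expect_equal(unname(unlist(g[625, ])), c(1, 1, 1, 1))
  # first column varies slowest, last fastest
  expect_equal(g$TGFb[1:5], seq(0, 1, by = 0.25))
  expect_true(all(diff(g$IFNg) >= 0))
  expect_error(grid_spec(IFNg = numeric(0)), "at least one level")
})

test_that("build_dataset pairs each grid row with its steady state", {
  d <- grid_dataset_raw()
  expect_s3_class(d, "sample_tbl")
  expect_equal(nrow(d), 625)
  zero_row <- d[d$IFNg == 0 & d$IL12 == 0 & d$IL6 == 0 & d$TGFb == 0, ]
  expect_equal(unname(unlist(zero_row[1, 5:9])), rep(0, 5))
  treg_row <- d[d$IFNg == 0 & d$IL12 == 0 & d$IL6 == 0 & d$TGFb == 1, ]
  expect_equal(treg_row$FOXP3[1], 16 / 17, tolerance = 1e-7)
})

test_that("normalization spans [0,1], is idempotent, handles degenerate columns", {
  base <- tibble::tibble(
    IFNg = c(0, 0.5, 1), IL12 = 0, IL6 = 0, TGFb = 0,
    IL17 = c(0, 0.4706, 0.9412), RORgt = c(1, 2, 4), IFNg_out = c(5, 5, 5),
    Tbet = c(0, 0.5, 1), FOXP3 = c(-1, 0, 3)
  )
  norm <- normalize_outputs(as_sample_table(base))
  expect_equal(norm$IL17, c(0, 0.5, 1), tolerance = 1e-12)
  expect_equal(norm$RORgt, c(0, 1 / 3, 1))
  expect_equal(norm$IFNg_out, c(0, 0, 0)) # degenerate rule
  expect_equal(norm$Tbet, c(0, 0.5, 1))   # identity when already [0,1]
  twice <- normalize_outputs(norm)
  expect_equal(unclass_tbl(twice)[5:9], unclass_tbl(norm)[5:9])
  sc <- sample_scaling(norm)
  expect_equal(sc$min[sc$output == "FOXP3"], -1)
  expect_equal(sc$max[sc$output == "FOXP3"], 3)
  expect_error(normalize_outputs(as_sample_table(base[1, ])), "2 rows")
})

test_that("output noise respects its bound, seed and zero level", {
  d <- small_table()
  expect_equal(
    as.data.frame(unclass_tbl(add_output_noise(d, 0, seed = 9))),
    as.data.frame(unclass_tbl(d))
  )
  n1 <- add_output_noise(d, 0.01, seed = 4)
  n2 <- add_output_noise(d, 0.01, seed = 4)
  expect_equal(as.data.frame(unclass_tbl(n1)), as.data.frame(unclass_tbl(n2)))
  n3 <- add_output_noise(d, 0.01, seed = 5)
  expect_false(isTRUE(all.equal(n1$IL17, n3$IL17)))
  Y0 <- as.matrix(tibble::as_tibble(d)[5:9])
  Y1 <- as.matrix(tibble::as_tibble(n1)[5:9])
  expect_true(all(abs(Y1 - Y0) <= 0.01 * Y0 + 1e-15))
  expect_equal(as.matrix(tibble::as_tibble(n1)[1:4]),
               as.matrix(tibble::as_tibble(d)[1:4]))
  expect_error(add_output_noise(d, -0.1), ">= 0")
})

test_that("noise is mean-preserving over many seeds", {
  d <- small_table()
  mu0 <- mean(d$IL17)
  mus <- vapply(1:40, function(s) {
    mean(add_output_noise(d, 0.01, seed = s)$IL17)
  }, numeric(1))
  # each cell perturbed by at most 1%, so averages stay within 1% too
  expect_lt(abs(mean(mus) - mu0), 0.01 * mu0)
})

test_that("splits are disjoint, exhaustive, seeded", {
  d <- grid_dataset()
  parts <- split_samples(d, n_train = 100, seed = 42)
  expect_equal(nrow(parts$train), 100)
  expect_equal(nrow(parts$test), 525)
  combined <- dplyr::bind_rows(unclass_tbl(parts$train),
                               unclass_tbl(parts$test)) |>
    dplyr::arrange(.data$IFNg, .data$IL12, .data$IL6, .data$TGFb)
  expect_equal(as.data.frame(combined),
               unclass_tbl(d) |>
                 dplyr::arrange(.data$IFNg, .data$IL12, .data$IL6,
                                .data$TGFb))
  again <- split_samples(d, n_train = 100, seed = 42)
  expect_equal(as.data.frame(unclass_tbl(parts$train)),
               as.data.frame(unclass_tbl(again$train)))
  other <- split_samples(d, n_train = 100, seed = 43)
  expect_false(isTRUE(all.equal(as.data.frame(unclass_tbl(parts$train)),
                                as.data.frame(unclass_tbl(other$train)))))
  expect_error(split_samples(d, n_train = 625), "strictly between")
  expect_error(split_samples(d, n_train = 0), "strictly between")
})

test_that("CSV round-trips losslessly and parses scientific notation", {
  path <- withr::local_tempfile(fileext = ".csv")
  d <- small_table()
  write_sample_csv(d, path)
  back <- read_sample_csv(path)
  expect_equal(as.data.frame(unclass_tbl(back)),
               as.data.frame(unclass_tbl(d)), tolerance = 1e-12)
  expect_equal(sample_scaling(back), sample_scaling(d))

  # published-style example row with a tiny FOXP3 in scientific notation
  fixture <- paste(
    "IFNg,IL12,IL6,TGFb,IL17,RORgt,IFNg_out,Tbet,FOXP3",
    "1,0,0.5,0,0.996,0.989,0.122,0.547,7.51E-06",
    "0.75,0.75,0,0.75,0.156,0.117,0.942,0.677,0.000103",
    sep = "\n"
  )
  fpath <- withr::local_tempfile(fileext = ".csv")
  writeLines(fixture, fpath)
  tab <- read_sample_csv(fpath)
  expect_equal(tab$FOXP3[1], 7.51e-6)
  expect_equal(unname(unlist(tab[1, 1:4])), c(1, 0, 0.5, 0))
})

test_that("malformed CSVs fail with located errors", {
  short <- "IFNg,IL12,IL6,TGFb\n0,0,0,0"
  p1 <- withr::local_tempfile(fileext = ".csv")
  writeLines(short, p1)
  expect_error(read_sample_csv(p1), "expected columns")

  bad <- paste(
    "IFNg,IL12,IL6,TGFb,IL17,RORgt,IFNg_out,Tbet,FOXP3",
    "0,0,0,0,0.1,0.2,abc,0.4,0.5",
    sep = "\n"
  )
  p2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(bad, p2)
  expect_error(read_sample_csv(p2), "row 1, column IFNg_out")
})
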