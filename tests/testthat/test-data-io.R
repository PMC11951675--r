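test_that("paired tables are read and aligned on their common samples", {
  dir <- withr::local_tempdir()
  paths <- rand_paired_files(dir, paste0("s", 1:4), paste0("s", 1:4), paste0("s", 1:4))
  pd <- read_paired_tables(paths[1], paths[2], paths[3])
  expect_s3_class(pd, "paired_data")
  expect_length(pd$sample_ids, 4L)
  expect_identical(rownames(pd$microbial), rownames(pd$metabolite))

  # metadata missing one sample: intersection semantics with a warning
  dir2 <- withr::local_tempdir()
  p2 <- rand_paired_files(dir2, paste0("s", 1:4), paste0("s", 1:4), paste0("s", 1:3))
  expect_warning(pd2 <- read_paired_tables(p2[1], p2[2], p2[3]), "dropped")
  expect_length(pd2$sample_ids, 3L)

  # disjoint sample sets are a hard error
  dir3 <- withr::local_tempdir()
  p3 <- rand_paired_files(dir3, paste0("s", 1:4), paste0("t", 1:4), paste0("s", 1:4))
  expect_error(read_paired_tables(p3[1], p3[2], p3[3]), "no overlapping samples")
})

test_that("non-numeric abundance cells are rejected with location info", {
  dir <- withr::local_tempdir()
  writeLines(c("sample_id\ttaxon1\ttaxon2", "s1\t1\toops", "s2\t2\t3"),
             file.path(dir, "microbial.tsv"))
  rand_paired_files(dir, character(0), paste0("s", 1:2), paste0("s", 1:2))[-1]
  # overwrite only metabolite/metadata; re-write microbial with the bad cell
  writeLines(c("sample_id\ttaxon1\ttaxon2", "s1\t1\toops", "s2\t2\t3"),
             file.path(dir, "microbial.tsv"))
  expect_error(
    read_paired_tables(file.path(dir, "microbial.tsv"),
                       file.path(dir, "metabolite.tsv"),
                       file.path(dir, "metadata.tsv")),
    "non-numeric")
})

make_pd <- function(mb, mt = NULL, labels = NULL) {
  mt <- mt %||% matrix(1, nrow(mb), 2)
  paired_data(mb, mt, labels = labels %||% rep("g", nrow(mb)))
}

test_that("sparse-feature filter removes strictly-more-than-threshold zeros", {
  mb <- cbind(a = c(0, 0, 0, 5),   # 75% zeros: removed
              b = c(0, 0, 3, 4),   # exactly 50%: retained
              c = 1:4)             # none: retained
  pd <- filter_sparse_features(make_pd(mb))
  expect_identical(colnames(pd$microbial), c("b", "c"))

  # all-positive table passes through untouched
  mb2 <- matrix(1:8, 4, 2)
  expect_equal(unname(filter_sparse_features(make_pd(mb2))$microbial), mb2)

  # removing everything is fatal
  mb3 <- matrix(c(0, 0, 0, 1), 4, 1)
  expect_error(filter_sparse_features(make_pd(mb3)), "zero-fraction")
})

test_that("zero replacement fills zeros and leaves nonzero entries alone", {
  pd <- make_pd(cbind(a = c(0, 2, 4)))
  out <- replace_zeros(pd)
  expect_equal(unname(out$microbial[, "a"]), c(1, 2, 4))  # 0.5 * min positive

  pd2 <- make_pd(cbind(a = c(1, 3)))
  expect_equal(unname(replace_zeros(pd2)$microbial[, "a"]), c(1, 3))

  pd3 <- make_pd(cbind(a = c(0, 0.001)))
  expect_equal(unname(replace_zeros(pd3, rule = "fixed", epsilon = 1e-6)$microbial[, "a"]),
               c(1e-6, 0.001))

  pd4 <- make_pd(cbind(a = c(0, 0)))
  expect_error(replace_zeros(pd4), "entirely zero")
})

test_that("clr transform matches its closed-form cases and identities", {
  pd <- make_pd(rbind(c(1, 1, 1, 1)))
  expect_equal(unname(clr_transform(pd, "microbial")$microbial[1, ]), rep(0, 4))

  pd2 <- make_pd(rbind(c(1, exp(2))))
  expect_equal(unname(clr_transform(pd2, "microbial")$microbial[1, ]), c(-1, 1))

  # any valid row sums to zero; clr is scale invariant
  set.seed(7)
  for (i in 1:25) {
    x <- matrix(rexp(6) + 1e-3, 1)
    out <- clr_transform(make_pd(x), "microbial")$microbial
    expect_lt(abs(sum(out)), 1e-9)
    out2 <- clr_transform(make_pd(x * runif(1, 0.01, 100)), "microbial")$microbial
    expect_equal(out, out2, tolerance = 1e-9)
  }

  expect_error(clr_transform(make_pd(rbind(c(0, 1)))), "replace_zeros")
})

test_that("the preprocessing pipeline is shape-idempotent and keeps alignment", {
  fx <- make_fixture("tiny", seed = 3)
  pd <- preprocess_paired(fx$data)
  expect_true(all(pd$transformed == "clr"))
  expect_lt(max(abs(rowSums(pd$microbial))), 1e-9)
  expect_lt(max(abs(rowSums(pd$metabolite))), 1e-9)
  expect_identical(pd$sample_ids, fx$data$sample_ids)
  expect_identical(pd$labels, fx$data$labels)

  # second pass on already-positive, non-sparse raw data changes nothing
  raw <- replace_zeros(filter_sparse_features(fx$data))
  raw2 <- replace_zeros(filter_sparse_features(raw))
  expect_equal(raw2$microbial, raw$microbial)
  expect_equal(raw2$metabolite, raw$metabolite)
})

test_that("datasets round-trip through disk with their transform flags", {
  fx <- make_fixture("tiny", seed = 4)
  pd <- preprocess_paired(fx$data)
  dir <- withr::local_tempdir()
  write_paired_tables(pd, dir)
  back <- read_paired_dir(dir)
  expect_equal(unname(back$microbial), unname(pd$microbial), tolerance = 1e-12)
  expect_identical(unname(back$transformed), c("clr", "clr"))
  expect_identical(back$labels, pd$labels)
})

test_that("as_tibble exposes sample ids and labels alongside features", {
  fx <- make_fixture("tiny", seed = 5)
  tb <- tibble::as_tibble(fx$data, table = "microbial")
  expect_identical(names(tb)[1:2], c("sample_id", "label"))
  expect_identical(nrow(tb), nrow(fx$data$microbial))
})
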