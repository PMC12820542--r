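test_that("the packaged 77-study effect table loads with its published structure", {
  ep <- read_effect_fixture()
  expect_s3_class(ep, "effect_points")
  expect_equal(nrow(ep), 77)
  expect_equal(sum(ep$country == "China"), 32)
  expect_equal(sum(ep$country != "China"), 45)
  # SE recomputed from n: spot-check against printed 3-decimal values
  expect_equal(round(ep$se_z[ep$dataset_id == "s01"], 3), 0.051)
  expect_equal(round(ep$se_z[ep$dataset_id == "s03"], 3), 0.080)
  # largest-SE study is the smallest one (n = 67)
  i <- which.max(ep$se_z)
  expect_equal(ep$z[i], 0.202)
  expect_equal(ep$se_z[i], 0.125)
  expect_false(ep$significant[i])
})

test_that("reading records parses significance labels and flags bad input", {
  csv <- paste(
    "dataset_id,predictor,outcome,beta,n,significance,country",
    "a,pe,bi,0.25,120,Significant,China",
    "b,pe,bi,,90,nonsignificant,France",
    "c,ee,bi,0.10,200,0,multiple",
    sep = "\n")
  recs <- read_path_records(textConnection(csv))
  expect_equal(nrow(recs), 3)
  expect_equal(recs$significant, c(TRUE, FALSE, FALSE))
  expect_true(is.na(recs$beta[2]))  # absent beta stays absent, never zero

  # header-only file is an empty, valid corpus
  empty <- read_path_records(textConnection(
    "dataset_id,predictor,outcome,beta,n,significance"))
  expect_equal(nrow(empty), 0)

  # n = 2 is accepted at read time; the meta-analysis rejects it later
  small <- read_path_records(textConnection(paste(
    "dataset_id,predictor,outcome,beta,n,significance",
    "tiny,pe,bi,0.2,2,significant", sep = "\n")))
  expect_equal(small$n, 2L)
  expect_error(effect_points(small, quiet = TRUE), "n - 3")

  expect_error(read_path_records(textConnection(
    "dataset_id,predictor,beta,n,significance\na,pe,0.1,50,1")),
    "outcome")
  expect_error(read_path_records(textConnection(paste(
    "dataset_id,predictor,outcome,n,significance",
    "a,pe,bi,many,1", sep = "\n"))), "row")
  expect_error(read_path_records(textConnection(paste(
    "dataset_id,predictor,outcome,n,significance",
    "a,pe,bi,50,probably", sep = "\n"))), "significance")
  expect_error(read_path_records(textConnection(paste(
    "dataset_id,predictor,outcome,n,significance",
    "a,pe,bi,50,1", "a,pe,bi,60,0", sep = "\n"))), "duplicate")
})

test_that("write/read round trip preserves field values", {
  recs <- make_records(beta = c(0.25, -0.123, NA), n = c(100, 250, 80),
                       significant = c(TRUE, FALSE, TRUE),
                       country = c("China", "France", "multiple"))
  f <- withr::local_tempfile(fileext = ".csv")
  write_path_records(recs, f)
  back <- read_path_records(f)
  expect_equal(as.data.frame(back)[names(recs)], as.data.frame(recs),
               tolerance = 0)
})

test_that("canonicalize is a logged, idempotent, single-pass rename", {
  recs <- make_records(beta = c(0.2, 0.3), n = 100,
                       predictor = c("perceived usefulness", "trust"),
                       outcome = c("intention to use", "intention to use"))
  map <- data.frame(alias = c("perceived usefulness", "intention to use"),
                    canonical = c("performance expectancy",
                                  "behavioral intention"))
  out <- canonicalize(recs, map, quiet = TRUE)
  expect_equal(out$predictor, c("performance expectancy", "trust"))
  expect_equal(unique(out$outcome), "behavioral intention")
  expect_equal(nrow(out), nrow(recs))
  # idempotent
  expect_equal(as.data.frame(canonicalize(out, map, quiet = TRUE)),
               as.data.frame(out))
  # empty map is the identity
  expect_equal(as.data.frame(canonicalize(recs, map[0, ], quiet = TRUE)),
               as.data.frame(recs))
  # single-pass: a -> b is not chased through b -> c
  chain <- data.frame(alias = c("a", "b"), canonical = c("b", "c"))
  r2 <- make_records(0.1, 50, predictor = "a", outcome = "bi")
  expect_equal(canonicalize(r2, chain, quiet = TRUE)$predictor, "b")
  # one alias, two targets is a configuration error
  expect_error(canonicalize(recs, data.frame(alias = c("x", "x"),
                                             canonical = c("y", "z"))),
               "multiple canonicals")
})

test_that("grouping applies the inclusion rule and conserves records", {
  recs <- path_records(data.frame(
    dataset_id = sprintf("d%d", 1:7),
    predictor = c("pe", "pe", "pe", "ee", "ee", "tr", "tr"),
    outcome = "bi",
    beta = 0.2, n = 100,
    significant = c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE, TRUE)))
  grp <- group_paths(recs, min_examinations = 3, quiet = TRUE)
  expect_equal(nrow(grp), 1)  # only pe -> bi reaches 3 examinations
  expect_equal(grp$S, 2)
  expect_equal(grp$E, 3)
  excl <- attr(grp, "excluded")
  expect_equal(nrow(excl), 2)
  expect_equal(sum(grp$E) + sum(excl$E), nrow(recs))
  # a two-record path is excluded at the default threshold
  expect_false("tr" %in% grp$predictor)
  # empty input yields empty output
  expect_equal(nrow(group_paths(recs[0, ], quiet = TRUE)), 0)
})

test_that("the reconstructed per-path count corpus reproduces the published grouping", {
  counts <- read_count_fixture()
  recs <- records_from_counts(counts)
  expect_equal(nrow(recs), sum(counts$total))
  grp <- group_paths(recs, min_examinations = 3, quiet = TRUE)
  expect_equal(nrow(grp), 67)
  expect_equal(length(unique(grp$predictor)), 31)
  bi <- grp[grp$outcome == "behavioral intention", ]
  expect_equal(nrow(bi), 25)
  # grouped counts agree with the published table row by row
  key <- function(d) paste(d$outcome, d$predictor)
  m <- match(key(grp), key(counts))
  expect_false(anyNA(m))
  expect_equal(grp$S, counts$significant[m])
  expect_equal(grp$E, counts$total[m])
})
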