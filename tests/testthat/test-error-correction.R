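# noisy full-design fixture: single+double KO matrices with injected errors
noisy_design <- function(g, fpr, fnr, seed) {
  a0 <- true_accessibility(g, character())
  extras <- lapply(gene_labels(g), function(s) true_accessibility(g, s))
  inject_errors(c(list(a0), extras), fpr, fnr, n_edges(g), seed = seed)
}

uncorrected <- function(mats) {
  closed <- lapply(mats, transitive_closure)
  suppressWarnings(infer_bounds(ensemble_spec(closed[[1]], closed[-1])))
}

test_that("majority pre-processing keeps frequent edges and drops rare ones", {
  labs <- paste0("G", 1:4)
  mk <- function(edges) {
    m <- matrix(0L, 4, 4, dimnames = list(labs, labs))
    for (e in edges) m[e[1], e[2]] <- 1L
    grn_accessibility(m)
  }
  common <- list(c(1, 2))
  mats <- c(replicate(7, mk(common), simplify = FALSE),
            replicate(3, mk(list()), simplify = FALSE))
  # edge present in 70% of matrices survives at threshold 0.65
  out <- preprocess_majority(mats, 0.65)
  expect_equal(sum(out[[1]]), 1)
  # present in 40%: removed everywhere
  mats2 <- c(replicate(4, mk(common), simplify = FALSE),
             replicate(6, mk(list()), simplify = FALSE))
  out2 <- preprocess_majority(mats2, 0.65)
  expect_true(all(vapply(out2, sum, numeric(1)) == 0))
  expect_error(preprocess_majority(mats, 0.9), "range")
  expect_warning(preprocess_majority(mats[1], 0.65), "pass-through")
})

test_that("pre-processing removes most randomly injected false positives", {
  set.seed(401)
  g <- random_dag(30, c(30, 40), seed = 77)
  a0 <- true_accessibility(g, character())
  mats <- replicate(100, a0, simplify = FALSE)
  noisy <- inject_errors(mats, fpr = 0.1, fnr = 0, n_edges(g))
  clean <- preprocess_majority(noisy, 0.65)
  injected <- Reduce(`|`, lapply(noisy, function(m) strip(m) & !strip(a0)))
  remaining <- Reduce(`|`, lapply(clean, function(m) strip(m) & !strip(a0)))
  expect_lt(sum(remaining) / sum(injected), 0.05)
  # true edges survive: they are present in every matrix
  expect_true(all(strip(clean[[1]]) >= strip(a0)))
})

test_that("inconsistent edge detection returns Type C and ignores Type B", {
  labs <- paste0("G", 1:3)
  lower <- grn_adjacency(rbind(c(0, 1, 0), c(0, 0, 0), c(0, 0, 0)), labs)
  upper <- grn_adjacency(rbind(c(0, 0, 1), c(0, 0, 0), c(0, 0, 0)), labs)
  bad <- detect_inconsistent_edges(lower, upper)
  expect_equal(nrow(bad), 1)          # the lower-only edge (Type C)
  expect_equal(unname(bad[1, ]), c(1, 2))
  expect_equal(nrow(detect_inconsistent_edges(lower, lower)), 0)
})

test_that("consistency check applies majority and tie rules", {
  labs <- paste0("G", 1:3)
  lower <- grn_adjacency(rbind(c(0, 1, 0), c(0, 0, 0), c(0, 0, 0)), labs)
  upper <- grn_adjacency(matrix(0, 3, 3), labs)
  ledger <- function(p, e) {
    pm <- matrix(0, 3, 3); em <- matrix(0, 3, 3)
    pm[1, 2] <- p; em[1, 2] <- e
    list(present = pm, eligible = em)
  }
  # 7 present vs 3 absent: added to upper, stays in lower
  b <- consistency_check(lower, upper, ledger(7, 10))
  expect_equal(b$lower["G1", "G2"], 1L, ignore_attr = TRUE)
  expect_equal(b$upper["G1", "G2"], 1L, ignore_attr = TRUE)
  # 3 present vs 7 absent: removed from lower
  b2 <- consistency_check(lower, upper, ledger(3, 10))
  expect_equal(b2$lower["G1", "G2"], 0L, ignore_attr = TRUE)
  expect_equal(b2$upper["G1", "G2"], 0L, ignore_attr = TRUE)
  # 5 vs 5 tie: in upper, out of lower (edge becomes non-inferable)
  b3 <- consistency_check(lower, upper, ledger(5, 10))
  expect_equal(b3$lower["G1", "G2"], 0L, ignore_attr = TRUE)
  expect_equal(b3$upper["G1", "G2"], 1L, ignore_attr = TRUE)
  expect_true(all(strip(b3$lower) <= strip(b3$upper)))
})

test_that("filtered bounds equal plain bounds on clean data and block
           non-testable false positives", {
  set.seed(402)
  g <- random_dag(10, c(8, 14), seed = 5)
  a0 <- true_accessibility(g, character())
  extras <- lapply(gene_labels(g), function(s) true_accessibility(g, s))
  raw_spec <- ensemble_spec(a0, extras)
  fb <- filtered_bounds(raw_spec, raw_spec)
  plain <- infer_bounds(raw_spec)
  expect_identical(strip(fb$lower_cand), strip(plain$lower))
  expect_identical(strip(fb$upper_cand_raw), strip(plain$upper))
  expect_identical(strip(fb$upper_cand_closed), strip(plain$upper))
  # errors at non-testable positions of an extra cannot reach the upper
  # bound: the filter ignores those entries entirely
  sig <- ko_background(extras[[1]])
  tm <- strip(testability_matrix(a0, sig)) != 0L
  free <- outer(!(gene_labels(g) %in% sig), !(gene_labels(g) %in% sig))
  m0 <- strip(extras[[1]])
  flip <- free & !tm & row(m0) != col(m0)
  m0[flip] <- 1L - m0[flip]  # corrupt every ignorable entry
  m0[sig, ] <- 0L; m0[, sig] <- 0L
  corrupted <- extras
  corrupted[[1]] <- grn_accessibility(m0, sigma = sig)
  fb2 <- filtered_bounds(ensemble_spec(a0, corrupted), raw_spec)
  expect_identical(strip(fb2$upper_cand_raw), strip(plain$upper))
})

test_that("upper candidate from raw matrices is never larger than from
           closed matrices", {
  set.seed(403)
  for (k in 1:8) {
    g <- random_dag(12, c(10, 20))
    mats <- noisy_design(g, fpr = 0.1, fnr = 0.1, seed = k)
    closed <- lapply(mats, transitive_closure)
    pre_raw <- preprocess_majority(mats, 0.65)
    pre_closed <- preprocess_majority(closed, 0.65)
    fb <- filtered_bounds(ensemble_spec(pre_raw[[1]], pre_raw[-1]),
                          ensemble_spec(pre_closed[[1]], pre_closed[-1]))
    expect_true(all(strip(fb$upper_cand_raw) <= strip(fb$upper_cand_closed)))
  }
})

test_that("corrected pipeline equals the plain one on error-free input", {
  set.seed(404)
  for (k in 1:20) {
    g <- if (k %% 2) random_dag(10, c(5, 20)) else random_grn(10, c(5, 20))
    a0 <- true_accessibility(g, character())
    extras <- lapply(gene_labels(g), function(s) true_accessibility(g, s))
    plain <- suppressWarnings(infer_bounds(ensemble_spec(a0, extras)))
    corrected <- infer_bounds_corrected(c(list(a0), extras))
    bad <- strip(plain$lower) & !strip(plain$upper)
    if (!any(bad)) {
      expect_identical(strip(corrected$lower), strip(plain$lower))
      expect_identical(strip(corrected$upper), strip(plain$upper))
    } else {
      # 2-node cycle expansion can make even clean plain bounds
      # inconsistent; the consistency check then resolves exactly those
      # positions and leaves everything else untouched
      expect_true(all(strip(corrected$lower) <= strip(corrected$upper)))
      expect_identical(strip(corrected$lower)[!bad], strip(plain$lower)[!bad])
      expect_identical(strip(corrected$upper)[!bad], strip(plain$upper)[!bad])
    }
  }
})

test_that("correction removes most injected errors and keeps bounds nested", {
  g <- random_dag(40, c(60, 80), seed = 88)
  for (rates in list(c(0.1, 0), c(0, 0.1), c(0.1, 0.1))) {
    mats <- noisy_design(g, rates[1], rates[2], seed = 90 + rates[1] * 10)
    eu <- classify_errors(g, uncorrected(mats))
    bc <- infer_bounds_corrected(mats)
    ec <- classify_errors(g, bc)
    expect_equal(ec$type_c, 0)
    expect_true(all(strip(bc$lower) <= strip(bc$upper)))
    expect_lt(ec$lower_fp + ec$upper_fn,
              0.5 * max(1, eu$lower_fp + eu$upper_fn))
  }
})

test_that("error classification matches the three patterns", {
  labs <- paste0("G", 1:3)
  truth <- grn_adjacency(rbind(c(0, 1, 0), c(0, 0, 1), c(0, 0, 0)), labs)
  perfect <- infer_bounds(full_design_spec(truth))
  e0 <- classify_errors(truth, perfect)
  expect_equal(e0$type_a + e0$type_b + e0$type_c, 0)
  # edge in both bounds but not in truth: Type A
  lower <- grn_adjacency(rbind(c(0, 1, 1), c(0, 0, 1), c(0, 0, 0)), labs)
  b <- tracegrn:::new_bounds(lower, lower)
  e1 <- classify_errors(truth, b)
  expect_equal(e1$type_a, 1)
  expect_equal(e1$lower_fp, 1)
  # edge in upper only: Type B regardless of truth
  up <- grn_adjacency(rbind(c(0, 1, 1), c(0, 0, 1), c(0, 0, 0)), labs)
  lo <- truth
  e2 <- classify_errors(truth, tracegrn:::new_bounds(lo, up))
  expect_equal(e2$type_b, 1)
  expect_equal(e2$type_c, 0)
})
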