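make_parcel_mi <- function(m, ids = NULL) {
  if (is.null(ids)) ids <- paste0("p", seq_len(nrow(m)))
  dimnames(m) <- list(ids, ids)
  structure(m, n_bins = 5L, diagonal = "entropy", class = c("parcel_mi", "matrix", "array"))
}

test_that("parcellation validation catches structural errors", {
  good <- tibble::tibble(
    parcel_id = c("p1", "p2", "p3"),
    region_id = c("r1", "r1", "r2"),
    lobe_id = c("L1", "L1", "L1")
  )
  expect_s3_class(parcellation(good), "parcellation")
  bad_dup <- good
  bad_dup$parcel_id[2] <- "p1"
  expect_error(parcellation(bad_dup), "duplicated parcel_id")
  bad_lobe <- good
  bad_lobe$lobe_id <- c("L1", "L2", "L1")
  expect_error(parcellation(bad_lobe), "more than one lobe")
  expect_error(parcellation(good[, 1:2]), "columns")
})

test_that("region MI reduces to the quantile of the enumerated parcel-pair list", {
  m <- matrix(0, 4, 4)
  m[1, 3] <- m[3, 1] <- 0.1
  m[1, 4] <- m[4, 1] <- 0.2
  m[2, 3] <- m[3, 2] <- 0.3
  m[2, 4] <- m[4, 2] <- 0.4
  pm <- make_parcel_mi(m)
  # interpolated order statistic at index 1 + (4 - 1) * 0.75 = 3.25
  expect_equal(region_mi(pm, c("p1", "p2"), c("p3", "p4")), 0.325)
  # singleton regions pass the parcel value through
  expect_equal(region_mi(pm, "p1", "p4"), 0.2)
  # intra-region: the C(3,2) = 3 unordered pairs, diagonal excluded
  m2 <- matrix(5, 3, 3)
  m2[1, 2] <- m2[2, 1] <- 0.1
  m2[1, 3] <- m2[3, 1] <- 0.2
  m2[2, 3] <- m2[3, 2] <- 0.6
  pm2 <- make_parcel_mi(m2)
  expect_equal(
    region_mi(pm2, c("p1", "p2", "p3"), c("p1", "p2", "p3")),
    oracle_quantile(c(0.1, 0.2, 0.6), 0.75)
  )
  expect_error(region_mi(pm, "p1", "p1"), "at least 2")
  expect_error(region_mi(pm, character(0), "p1"), "non-empty")
  expect_error(region_mi(pm, "p1", "nope"), "unknown")
})

test_that("region MI is symmetric, bounded by the list extremes, monotone in the quantile", {
  set.seed(10)
  for (rep in 1:10) {
    m <- matrix(0, 6, 6)
    v <- runif(15)
    m[upper.tri(m)] <- v
    m <- m + t(m)
    pm <- make_parcel_mi(m)
    a <- c("p1", "p2", "p3")
    b <- c("p4", "p5", "p6")
    expect_identical(region_mi(pm, a, b), region_mi(pm, b, a))
    vals <- as.vector(m[1:3, 4:6])
    got <- region_mi(pm, a, b)
    expect_gte(got, min(vals))
    expect_lte(got, max(vals))
    expect_equal(got, oracle_quantile(vals, 0.75), tolerance = 1e-12)
    # the four quantile levels explored for the aggregation statistic
    curve <- vapply(c(0.70, 0.75, 0.80, 0.85), function(q) region_mi(pm, a, b, q), numeric(1))
    expect_true(all(diff(curve) >= 0))
  }
})

test_that("region and lobe matrices: symmetry, set semantics, translation equivariance", {
  set.seed(11)
  co <- small_cohort(seed = 3, subjects_per_class = 2, n_timepoints = 80)
  mi <- pairwise_mi_matrix(co$time_series[[1]])
  parc <- co$parcellation
  rm <- region_mi_matrix(mi, parc)
  expect_s3_class(rm, "region_mi")
  expect_identical(rownames(rm), unique(parc$region_id))
  expect_identical(unclass(rm), t(unclass(rm)))
  expect_identical(attr(rm, "quantile_level"), 0.75)

  # permuting parcel rows of the input leaves the aggregation unchanged
  perm <- sample(nrow(mi))
  mi_perm <- structure(unclass(mi)[perm, perm],
    n_bins = 5L, diagonal = "entropy",
    class = c("parcel_mi", "matrix", "array")
  )
  expect_equal(unclass(region_mi_matrix(mi_perm, parc)), unclass(rm))

  # adding a constant shifts every aggregated entry by that constant
  mi_shift <- structure(unclass(mi) + 0.3,
    n_bins = 5L, diagonal = "entropy",
    class = c("parcel_mi", "matrix", "array")
  )
  expect_equal(unclass(region_mi_matrix(mi_shift, parc)), unclass(rm) + 0.3)

  lm <- lobe_mi_matrix(mi, parc)
  expect_identical(dim(unclass(lm)), c(10L, 10L))
  expect_identical(unclass(lm), t(unclass(lm)))

  # one region per lobe: the two scales coincide
  parc1 <- parc
  parc1$lobe_id <- parc1$region_id
  expect_equal(unclass(lobe_mi_matrix(mi, parc1)), unclass(region_mi_matrix(mi, parc)),
    ignore_attr = TRUE
  )
})

test_that("lobe driver analysis finds the region coupling strongly with both A and B", {
  ids <- c("rA", "rB", "k1", "k2", "k3")
  m <- matrix(0.05, 5, 5, dimnames = list(ids, ids))
  m["k2", "rA"] <- m["rA", "k2"] <- 0.30
  m["k2", "rB"] <- m["rB", "k2"] <- 0.28
  m["k3", "rA"] <- m["rA", "k3"] <- 0.40  # strong with A only
  rm <- structure(m, quantile_level = 0.75, level = "region", class = c("region_mi", "matrix", "array"))
  parc <- tibble::tibble(
    parcel_id = paste0("x", 1:5),
    region_id = ids,
    lobe_id = c("LX", "LX", "LK", "LK", "LK")
  )
  out <- lobe_driver_analysis(rm, c("rA", "rB"), "LK", parc)
  expect_identical(out$region, c("k1", "k2", "k3"))
  expect_equal(out$min_mi, pmin(out$mi_a, out$mi_b))
  expect_identical(out$region[out$is_driver], "k2")

  # all couplings equal: first region in identifier order wins the tie
  m2 <- matrix(0.2, 5, 5, dimnames = list(ids, ids))
  rm2 <- structure(m2, quantile_level = 0.75, level = "region", class = c("region_mi", "matrix", "array"))
  out2 <- lobe_driver_analysis(rm2, c("rA", "rB"), "LK", parc)
  expect_identical(out2$region[out2$is_driver], "k1")

  expect_error(lobe_driver_analysis(rm, c("rA", "rB"), "nope", parc), "no region")
})
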