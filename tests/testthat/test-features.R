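test_that("German-tank interval extends [min, max] by range/(s - 1)", {
  expect_equal(german_tank_interval(c(0, 1)), c(lower = -1, upper = 2))
  expect_equal(german_tank_interval(1:5), c(lower = 0, upper = 6))
  expect_equal(german_tank_interval(rep(3.2, 6)), c(lower = 3.2, upper = 3.2))
  expect_error(german_tank_interval(5), "at least 2")
})

test_that("separability: disjoint 1, nested 0, partial overlap in between", {
  expect_equal(separability(c(0, 1), c(5, 6)), 1)
  expect_equal(separability(c(0, 10), c(2, 3)), 0)
  expect_equal(separability(c(2, 3), c(0, 10)), 0)
  expect_equal(separability(c(0, 2), c(1, 3)), 0.5)
  expect_equal(separability(c(0, 1), c(1, 2)), 1)  # touching: empty-length overlap
  # degenerate intervals: disjoint points 1, coincident or contained 0
  expect_equal(separability(c(2, 2), c(3, 3)), 1)
  expect_equal(separability(c(2, 2), c(2, 2)), 0)
  expect_equal(separability(c(2, 2), c(0, 5)), 0)
  set.seed(12)
  for (i in 1:50) {
    j <- sort(runif(2)); j2 <- sort(runif(2))
    s <- separability(j, j2)
    expect_gte(s, 0)
    expect_lte(s, 1)
    expect_identical(s, separability(j2, j))
    disjoint <- j[2] <= j2[1] || j2[2] <= j[1]
    expect_identical(s == 1, disjoint)
  }
  expect_error(separability(c(2, 1), c(0, 1)), "lower")
})

test_that("discriminating power: symmetry, affine invariance, edge examples", {
  expect_equal(discriminating_power(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(discriminating_power(c(0, 1), c(10, 11)), 1)
  set.seed(13)
  for (i in 1:20) {
    vp <- rnorm(5)
    vq <- rnorm(7, mean = 1)
    expect_identical(discriminating_power(vp, vq), discriminating_power(vq, vp))
    a <- runif(1, 0.5, 3)
    b <- rnorm(1)
    expect_equal(
      discriminating_power(a * vp + b, a * vq + b),
      discriminating_power(vp, vq),
      tolerance = 1e-12
    )
  }
})

test_that("feature enumeration covers the region-pair pool", {
  fp <- feature_pairs(sprintf("R%03d", 1:148))
  expect_identical(nrow(fp), 11026L)  # 148 * 149 / 2
  expect_identical(nrow(feature_pairs(sprintf("R%03d", 1:148), "inter")), 10878L)
  expect_identical(nrow(feature_pairs(sprintf("R%03d", 1:148), "intra")), 148L)
  fp4 <- feature_pairs(c("a", "b", "c", "d"))
  expect_identical(fp4$feature[1:4], c("a_a", "a_b", "a_c", "a_d"))
})

test_that("selection enumerates 10 tasks, 20 selections, trims to 18 by power", {
  fix <- separable_cohort(k = 5, per_class = 4, n_noise = 30, seed = 21)
  sel <- select_features(fix$table, fix$membership)
  expect_identical(nrow(class_tasks(sprintf("C%d", 1:5))), 10L)
  expect_identical(nrow(sel$selections), 20L)
  expect_lte(nrow(sel$selected), 18L)
  expect_true(all(sel$selections$power >= 0 & sel$selections$power <= 1))
  # the class-j marker feature separates every task involving class j
  markers <- sprintf("R%03d_R%03d", 1:5, 6:10)
  expect_true(all(markers %in% sel$selected$feature))
})

test_that("a constructed pool with exactly two unit-power features per task selects those and trims deterministically", {
  classes <- sprintf("C%d", 1:5)
  tasks <- class_tasks(classes)
  n_per <- 3
  membership <- tibble::tibble(
    subject_id = sprintf("s%02d", 1:(5 * n_per)),
    classes = as.list(rep(classes, each = n_per))
  )
  prim <- rep(classes, each = n_per)
  tab <- tibble::tibble(subject_id = membership$subject_id)
  # feature 2t-1 and 2t separate task t perfectly, all others are flat
  for (t in seq_len(nrow(tasks))) {
    for (slot in 1:2) {
      f <- sprintf("R%03d_R%03d", 2 * t - 1 + 20 * (slot - 1), 2 * t + 20 * (slot - 1))
      v <- numeric(length(prim))
      v[prim == tasks$class_p[t]] <- 10 + seq_len(n_per)
      v[prim == tasks$class_q[t]] <- -10 - seq_len(n_per)
      # uninvolved classes span both sides: nested intervals, power 0
      v[v == 0] <- c(-15, 0, 15)
      tab[[f]] <- v
    }
  }
  sel <- select_features(tab, membership, per_task = 2, max_features = 18)
  expect_identical(nrow(sel$selections), 20L)
  expect_true(all(sel$selections$power == 1))
  expect_identical(nrow(sel$candidates), 20L)
  expect_identical(nrow(sel$selected), 18L)
  # the two dropped are the lexicographically last among the all-tied pool
  dropped <- setdiff(sel$candidates$feature, sel$selected$feature)
  ordered <- sort(sel$candidates$feature)
  expect_identical(sort(dropped), tail(ordered, 2))
})

test_that("selection is invariant to subject relabeling and per-column affine maps", {
  fix <- separable_cohort(k = 3, per_class = 4, n_noise = 5, seed = 22)
  sel <- select_features(fix$table, fix$membership)
  # shuffle subject rows
  perm <- sample(nrow(fix$table))
  sel2 <- select_features(fix$table[perm, ], fix$membership)
  expect_identical(sel$selected$feature, sel2$selected$feature)
  expect_equal(sel$selected$power, sel2$selected$power)
  # positive affine transform of one feature column
  tab3 <- fix$table
  tab3[[2]] <- 3.7 * tab3[[2]] + 11
  sel3 <- select_features(tab3, fix$membership)
  expect_identical(sel$selected$feature, sel3$selected$feature)
  expect_equal(sel$selected$power, sel3$selected$power, tolerance = 1e-10)
})

test_that("dual-class subjects contribute to both classes' value lists", {
  membership <- tibble::tibble(
    subject_id = sprintf("s%d", 1:5),
    classes = list("C1", "C1", c("C1", "C2"), "C2", "C2")
  )
  tab <- tibble::tibble(
    subject_id = membership$subject_id,
    R001_R002 = c(0, 1, 5, 10, 11)
  )
  sel <- select_features(tab, membership, per_task = 1, max_features = 5)
  # V(C1) = (0, 1, 5), V(C2) = (5, 10, 11): shared value 5 keeps the
  # German-tank intervals overlapping, so power < 1
  expect_lt(sel$selections$power, 1)
  expect_equal(
    sel$selections$power,
    discriminating_power(c(0, 1, 5), c(5, 10, 11))
  )
})

test_that("intra-region selection restricts the pool to diagonal features", {
  fix <- separable_cohort(k = 3, per_class = 4, n_noise = 3, seed = 23)
  tab <- fix$table
  tab$R050_R050 <- ifelse(fix$classes == "C1", 8, 0) + rnorm(nrow(tab), sd = 0.05)
  tab$R060_R060 <- ifelse(fix$classes == "C2", 8, 0) + rnorm(nrow(tab), sd = 0.05)
  tab$R070_R070 <- ifelse(fix$classes == "C3", 8, 0) + rnorm(nrow(tab), sd = 0.05)
  sel <- select_intra_features(tab, fix$membership)
  expect_true(all(sel$selections$region_a == sel$selections$region_b))
  expect_true(all(c("R050_R050", "R060_R060", "R070_R070") %in% sel$selected$feature))
  expect_lte(nrow(sel$selections), 2 * 3)
  # max_features above the candidate count keeps everything
  sel_all <- select_intra_features(tab, fix$membership, max_features = 100)
  expect_identical(nrow(sel_all$selected), nrow(sel_all$candidates))
  expect_error(select_intra_features(fix$table[1:4], fix$membership), "intra")
})

test_that("per-task planted columns are recovered across 40 seeded cohorts", {
  classes <- sprintf("C%d", 1:3)
  tasks <- class_tasks(classes)
  hits <- 0L
  total <- 0L
  for (seed in 1:40) {
    set.seed(seed)
    n_per <- 5
    prim <- rep(classes, each = n_per)
    tab <- tibble::tibble(subject_id = sprintf("s%02d", seq_along(prim)))
    planted <- character(nrow(tasks))
    for (t in seq_len(nrow(tasks))) {
      f <- sprintf("R%03d_R%03d", 100 + t, 110 + t)
      planted[t] <- f
      v <- rnorm(length(prim))
      # shift the q-class by >= 4 pooled SDs for this task only; classes
      # not in the task span the whole range, so their nested intervals
      # keep this column from also winning other tasks
      v[prim == tasks$class_q[t]] <- v[prim == tasks$class_q[t]] + 8
      uninvolved <- !(prim %in% c(tasks$class_p[t], tasks$class_q[t]))
      v[uninvolved] <- runif(sum(uninvolved), -4, 12)
      tab[[f]] <- v
    }
    for (j in 1:10) tab[[sprintf("R%03d_R%03d", j, j + 50)]] <- rnorm(length(prim))
    membership <- tibble::tibble(subject_id = tab$subject_id, classes = as.list(prim))
    sel <- select_features(tab, membership, per_task = 2)
    for (t in seq_len(nrow(tasks))) {
      task_rows <- sel$selections[
        sel$selections$class_p == tasks$class_p[t] & sel$selections$class_q == tasks$class_q[t],
      ]
      total <- total + 1L
      if (planted[t] %in% task_rows$feature) hits <- hits + 1L
    }
  }
  expect_gte(hits / total, 0.95)
})
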