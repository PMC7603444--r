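#' Configuration of a synthetic labeled cohort
#'
#' Describes the world the pipeline assumes: a lobes/regions/parcels
#' hierarchy, per-subject parcel time series built from region-level
#' latent signals plus parcel noise, and class-dependent couplings. For
#' every two-class discrimination task (p, q) with p < q one region pair
#' (A, B) is planted: subjects of class p share an extra latent factor
#' injected into both A and B at strength `coupling_strength`, subjects
#' of class q have no coupling there, and subjects of the remaining
#' classes draw a heterogeneous coupling uniform on
#' `[0, coupling_strength]` — so the coefficient MIreg(A, B) cleanly
#' separates p from q while the uninvolved classes span the whole range
#' (their wide value intervals give the pair near-zero power for every
#' other task, making each task's own pair its best discriminator: the
#' regime the selection algorithm assumes). Region latents are
#' renormalized to unit variance after factor injection, so a planted
#' factor changes only inter-region coupling, never a region's own
#' marginal latent share. A small
#' fraction of subjects is ambiguously diagnosed (two classes, each
#' coupling at half strength), mirroring the 4-of-46 dual diagnoses of
#' the motivating cohort. An optional unknown strictly increasing
#' per-parcel distortion emulates the unobservable BOLD-to-measurement
#' response.
#'
#' Defaults state the reference world: 5 classes x 9 subjects, 10 lobes
#' x 2 regions x 3 parcels (a reduced geometry; the full anatomy would be
#' 148 regions / 780 parcels), 295 time points per series (300 acquired
#' volumes minus the 5 discarded for magnetization equilibrium), unit
#' region latents and unit parcel noise, coupling strength 2.5 (carrier
#' parcel-pair correlation about 0.43, an order of magnitude above the
#' plug-in MI noise floor at n = 295).
#'
#' @param n_classes Number of diagnostic classes (default 5).
#' @param subjects_per_class Subjects per class (default 9).
#' @param n_lobes,regions_per_lobe,parcels_per_region Geometry (defaults
#'   10, 2, 3).
#' @param n_timepoints Time points per parcel series (default 295).
#' @param coupling_strength Scale of the planted shared factor (default
#'   2.5).
#' @param noise_sd Parcel-level noise SD (default 1).
#' @param distortion `"none"` or `"monotone"` (random strictly increasing
#'   per-parcel maps).
#' @param dual_fraction Fraction of subjects flagged dual-class (default
#'   4/46).
#' @param planted_pairs Optional tibble `class_p`, `class_q`,
#'   `region_a`, `region_b`; assigned automatically when `NULL` (one
#'   disjoint region pair per task, in task order).
#' @param seed Master seed; the cohort is reproducible from the config
#'   alone.
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(n_classes = 5L, subjects_per_class = 9L, n_lobes = 10L,
                          regions_per_lobe = 2L, parcels_per_region = 3L,
                          n_timepoints = 295L, coupling_strength = 2.5,
                          noise_sd = 1, distortion = c("none", "monotone"),
                          dual_fraction = 4 / 46, planted_pairs = NULL,
                          seed = 1L) {
  distortion <- match.arg(distortion)
  cfg <- list(
    n_classes = as.integer(n_classes),
    subjects_per_class = as.integer(subjects_per_class),
    n_lobes = as.integer(n_lobes),
    regions_per_lobe = as.integer(regions_per_lobe),
    parcels_per_region = as.integer(parcels_per_region),
    n_timepoints = as.integer(n_timepoints),
    coupling_strength = as.double(coupling_strength),
    noise_sd = as.double(noise_sd),
    distortion = distortion,
    dual_fraction = as.double(dual_fraction),
    planted_pairs = planted_pairs,
    seed = as.integer(seed)
  )
  counts <- c(
    cfg$n_classes, cfg$subjects_per_class, cfg$n_lobes,
    cfg$regions_per_lobe, cfg$parcels_per_region, cfg$n_timepoints
  )
  if (anyNA(counts) || any(counts < 1)) abort("all counts must be >= 1.")
  if (cfg$noise_sd <= 0) abort("`noise_sd` must be positive.")
  if (cfg$coupling_strength < 0) abort("`coupling_strength` must be non-negative.")
  if (cfg$dual_fraction < 0 || cfg$dual_fraction >= 1) abort("`dual_fraction` must lie in [0, 1).")
  n_regions <- cfg$n_lobes * cfg$regions_per_lobe
  region_ids <- sprintf("R%03d", seq_len(n_regions))
  if (is.null(cfg$planted_pairs)) {
    tasks <- class_tasks(sprintf("C%d", seq_len(cfg$n_classes)))
    if (n_regions < 2 * nrow(tasks)) {
      abort(sprintf(
        "%d regions cannot host %d disjoint planted pairs; enlarge the geometry or supply `planted_pairs`.",
        n_regions, nrow(tasks)
      ))
    }
    tasks$region_a <- region_ids[2 * seq_len(nrow(tasks)) - 1]
    tasks$region_b <- region_ids[2 * seq_len(nrow(tasks))]
    cfg$planted_pairs <- tasks
  } else {
    pp <- tibble::as_tibble(planted_pairs)
    if (!all(c("class_p", "class_q", "region_a", "region_b") %in% names(pp))) {
      abort("`planted_pairs` needs columns class_p, class_q, region_a, region_b.")
    }
    if (!all(c(pp$region_a, pp$region_b) %in% region_ids)) {
      abort("`planted_pairs` references regions outside the parcellation.")
    }
    cfg$planted_pairs <- pp
  }
  structure(cfg, class = "cohort_config")
}

cohort_parcellation <- function(config) {
  n_regions <- config$n_lobes * config$regions_per_lobe
  region_ids <- sprintf("R%03d", seq_len(n_regions))
  lobe_ids <- sprintf("L%02d", rep(seq_len(config$n_lobes), each = config$regions_per_lobe))
  parcellation(tibble::tibble(
    parcel_id = sprintf("P%04d", seq_len(n_regions * config$parcels_per_region)),
    region_id = rep(region_ids, each = config$parcels_per_region),
    lobe_id = rep(lobe_ids, each = config$parcels_per_region)
  ))
}

#' Generate a seeded synthetic cohort
#'
#' Draws, per subject, iid standard-normal latent signals for every
#' region, adds the planted shared factors for the classes the subject
#' carries (half strength for dual-class subjects), and emits each parcel
#' as its region's latent plus independent noise. All randomness flows
#' from `config$seed`; the same config yields a byte-identical cohort.
#'
#' @param config A [cohort_config()].
#' @return Object of class `synthetic_cohort`: list with `time_series`
#'   (named list of parcels x time matrices), `parcellation`,
#'   `membership` (tibble of class sets), `planted` (ground-truth region
#'   pairs per task) and `config`.
#' @examples
#' co <- generate_cohort(cohort_config(subjects_per_class = 2, n_timepoints = 60))
#' names(co)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  parc <- cohort_parcellation(config)
  classes <- sprintf("C%d", seq_len(config$n_classes))
  n_sub <- config$n_classes * config$subjects_per_class
  subject_ids <- sprintf("sub%02d", seq_len(n_sub))
  primary <- rep(classes, each = config$subjects_per_class)
  # first subject of class p is flagged dual (second class: the next class,
  # wrapping), until the dual budget round(dual_fraction * n) is spent
  n_dual <- min(round(config$dual_fraction * n_sub), config$n_classes)
  class_sets <- lapply(seq_len(n_sub), function(i) primary[i])
  for (d in seq_len(n_dual)) {
    i <- (d - 1) * config$subjects_per_class + 1
    second <- classes[d %% config$n_classes + 1]
    class_sets[[i]] <- c(primary[i], second)
  }
  membership <- class_membership(tibble::tibble(subject_id = subject_ids, classes = class_sets))

  region_ids <- unique(parc$region_id)
  n_regions <- length(region_ids)
  Tn <- config$n_timepoints
  old <- local_seed(config$seed)
  on.exit(restore_seed(old), add = TRUE)
  series <- vector("list", n_sub)
  names(series) <- subject_ids
  pp <- config$planted_pairs
  for (i in seq_len(n_sub)) {
    latent <- matrix(rnorm(n_regions * Tn), n_regions, Tn, dimnames = list(region_ids, NULL))
    factor_var <- setNames(numeric(n_regions), region_ids)
    cls <- class_sets[[i]]
    dual <- length(cls) == 2
    for (r in seq_len(nrow(pp))) {
      # role of this subject on the pair of task (p, q): carrier of p ->
      # full (half when dual-diagnosed), carrier of q -> none, uninvolved
      # -> heterogeneous background coupling over the whole range
      strength <- if (pp$class_p[r] %in% cls) {
        config$coupling_strength * (if (dual) 0.5 else 1)
      } else if (pp$class_q[r] %in% cls) {
        0
      } else {
        runif(1, 0, config$coupling_strength)
      }
      g <- rnorm(Tn)
      if (strength > 0) {
        for (reg in c(pp$region_a[r], pp$region_b[r])) {
          latent[reg, ] <- latent[reg, ] + strength * g
          factor_var[reg] <- factor_var[reg] + strength^2
        }
      }
    }
    # renormalize each region latent to unit variance so a planted factor
    # changes only the *coupling* between regions, never a region's own
    # marginal latent share (intra-region connectivity stays flat)
    latent <- latent / sqrt(1 + factor_var)
    m <- latent[parc$region_id, , drop = FALSE] +
      config$noise_sd * matrix(rnorm(nrow(parc) * Tn), nrow(parc), Tn)
    rownames(m) <- parc$parcel_id
    series[[i]] <- m
  }
  if (config$distortion == "monotone") {
    for (i in seq_len(n_sub)) {
      series[[i]] <- apply_monotone_distortion(series[[i]], seed = child_seed(config$seed, i))
    }
  }
  structure(
    list(
      time_series = series, parcellation = parc, membership = membership,
      planted = config$planted_pairs, config = config
    ),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "<synthetic_cohort> %d subjects (%d classes), %d parcels / %d regions / %d lobes, T = %d, coupling %.2f, distortion %s\n",
    length(x$time_series), x$config$n_classes, nrow(x$parcellation),
    length(unique(x$parcellation$region_id)), length(unique(x$parcellation$lobe_id)),
    x$config$n_timepoints, x$config$coupling_strength, x$config$distortion
  ))
  invisible(x)
}

#' Apply random strictly increasing per-parcel distortions
#'
#' Emulates the unknown monotone measurement response between true BOLD
#' signal and recorded values: each parcel row is passed through its own
#' random map `b + a x + c x^3 + d exp(e x)` with a, c, d, e > 0 —
#' strictly increasing, generally non-linear. Because discretization is
#' rank-based, every downstream mutual-information quantity is exactly
#' unchanged.
#'
#' @param ts Parcel time series (matrix or data frame).
#' @param seed Seed for the per-parcel coefficient draws.
#' @return Distorted matrix with the same dimnames.
#' @export
apply_monotone_distortion <- function(ts, seed = 1L) {
  m <- as_time_series_matrix(ts)
  old <- local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  for (i in seq_len(nrow(m))) {
    a <- runif(1, 0.5, 2)
    b <- runif(1, -1, 1)
    cc <- runif(1, 0.01, 0.1)
    d <- runif(1, 0.1, 1)
    e <- runif(1, 0.1, 0.5)
    x <- m[i, ]
    m[i, ] <- b + a * x + cc * x^3 + d * exp(e * x)
  }
  m
}
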