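PROTOTYPE_SHAPES <- c("monotone-decay", "late-rise", "mid-peak", "relapse",
                      "flat-high", "flat-low", "early-peak")

#' Prototype symptom trajectory shapes
#'
#' Deterministic template trajectories on the 0--4 score scale, evaluated on
#' an integer visit grid. The six core shapes are built from three temporal
#' contrasts that a one-visit warping band cannot align away -- linear trend,
#' curvature, and overall level -- each in both directions around the
#' mid-scale: acute resolution (`monotone-decay`) versus late-emerging
#' burden (`late-rise`), a mid-follow-up peak (`mid-peak`) versus an acute
#' course with late recurrence (`relapse`), and persistently high
#' (`flat-high`) versus background-level (`flat-low`) symptoms. This makes
#' the planted clusters comparably separated in DTW space. `early-peak`
#' (a post-discharge flare) is a seventh shape used mainly to exercise
#' lead-lag alignment.
#'
#' @param shape One of `"monotone-decay"`, `"late-rise"`, `"mid-peak"`,
#'   `"relapse"`, `"flat-high"`, `"flat-low"`, `"early-peak"`.
#' @param visits Integer visit indices (default `0:5`).
#' @return Numeric trajectory in \[0, 4\].
#' @export
#' @examples
#' prototype_trajectory("monotone-decay")
prototype_trajectory <- function(shape, visits = 0:5) {
  if (!shape %in% PROTOTYPE_SHAPES) {
    stop("unknown shape '", shape, "'; library: ",
         paste(PROTOTYPE_SHAPES, collapse = ", "))
  }
  t <- visits / max(max(visits), 1)
  q <- (t - 0.5)^2
  curv <- (q - mean(q)) / max(abs(q - mean(q)))
  v <- switch(shape,
    "monotone-decay" = 2 - 1.8 * (2 * t - 1),
    "late-rise" = 2 + 1.8 * (2 * t - 1),
    "mid-peak" = 2 - 1.8 * curv,
    "relapse" = 2 + 1.8 * curv,
    "flat-high" = rep(2.85, length(t)),
    "flat-low" = rep(1.15, length(t)),
    "early-peak" = 0.3 + 3.5 * exp(-((t - 0.2) / 0.18)^2))
  pmin(4, pmax(0, v))
}

#' Default planted cluster structure
#'
#' Partitions the 32-item catalogue into six clusters with the sizes
#' 3/1/12/10/4/2 and one distinct prototype shape each, mirroring the
#' cluster granularity reported for acute-pancreatitis symptom panels
#' (emotional, appetite, multi-system, localized-perception, functional
#' decline, abdominal).
#'
#' @param symptoms Symptom identifier vector (default the 32-item
#'   catalogue).
#' @return List of cluster specs: `cluster_id`, `members`, `shape`.
#' @export
default_cluster_spec <- function(symptoms = msas_catalogue()$symptom_id) {
  spec <- list(
    list(cluster_id = 1L, shape = "relapse",
         members = c("S24", "S16", "S18")),
    list(cluster_id = 2L, shape = "mid-peak",
         members = "S21"),
    list(cluster_id = 3L, shape = "flat-high",
         members = c("S07", "S05", "S01", "S08", "S29", "S22",
                     "S28", "S15", "S17", "S13", "S14", "S04")),
    list(cluster_id = 4L, shape = "flat-low",
         members = c("S25", "S23", "S12", "S20", "S30", "S09",
                     "S32", "S26", "S31", "S19")),
    list(cluster_id = 5L, shape = "late-rise",
         members = c("S10", "S03", "S27", "S06")),
    list(cluster_id = 6L, shape = "monotone-decay",
         members = c("S11", "S02")))
  if (!setequal(unlist(lapply(spec, `[[`, "members")), symptoms)) {
    # rebuild a balanced spec for non-default catalogues
    groups <- split(symptoms,
                    rep(1:6, length.out = length(symptoms)))
    spec <- lapply(seq_along(groups), function(i) {
      list(cluster_id = i, shape = PROTOTYPE_SHAPES[i],
           members = unname(groups[[i]]))
    })
  }
  spec
}

#' Balanced well-separated cluster structure
#'
#' Partitions the symptom set into six clusters of near-equal size, one per
#' core prototype shape. With comparable sizes and the comparably separated
#' shape library this is the "strongly separated planted clusters"
#' condition under which the planted cluster count is identifiable by the
#' SSE curvature criterion.
#'
#' @param symptoms Symptom identifier vector (default the 32-item
#'   catalogue).
#' @param sizes Cluster sizes summing to `length(symptoms)` (default
#'   `c(6, 6, 5, 5, 5, 5)`).
#' @return List of cluster specs, as in [default_cluster_spec()].
#' @export
balanced_cluster_spec <- function(symptoms = msas_catalogue()$symptom_id,
                                  sizes = c(6, 6, 5, 5, 5, 5)) {
  if (sum(sizes) != length(symptoms)) {
    stop("cluster sizes must sum to the number of symptoms")
  }
  groups <- split(symptoms, rep(seq_along(sizes), times = sizes))
  lapply(seq_along(groups), function(i) {
    list(cluster_id = i, shape = PROTOTYPE_SHAPES[i],
         members = unname(groups[[i]]))
  })
}

#' Simulation configuration for a synthetic MSAS-like cohort
#'
#' Defaults mirror the study cohort: 155 patients, the 32-item catalogue,
#' six equally indexed visits, and six planted clusters. Patient-level
#' temporal shifts are integer visit offsets (trajectories are evaluated on
#' a shifted, edge-padded index because the DTW band is declared in visit
#' units).
#'
#' @param n_patients Cohort size before any attrition (default 155).
#' @param n_symptoms Number of symptoms (default 32; must match the
#'   cluster spec).
#' @param n_visits Number of visit-grid points (default 6).
#' @param cluster_spec Planted structure (see [default_cluster_spec()]).
#' @param shift_sd SD of the patient-level temporal shift, in visit units
#'   (shifts are rounded to integers and clamped to two visits).
#' @param amplitude_sd SD of the per-(patient, symptom) multiplicative
#'   amplitude around 1.
#' @param noise_sd SD of the additive Gaussian measurement noise on the
#'   0--4 scale.
#' @param leadlag_pairs List of `list(driver =, follower =, lag =)` with
#'   integer lags >= 1 (in visits): the follower's trajectory becomes a
#'   time-delayed copy of its driver's plus noise.
#' @param missing_visit_prob Probability that a follow-up visit (all but
#'   baseline) is unobserved.
#' @param n_complete Optional exact number of patients left fully observed;
#'   the remaining patients are forced to miss at least one follow-up visit
#'   (emulates an enrolled-vs-completed attrition flow such as 226 -> 155).
#' @param ordinal_rounding Round scores to the MSAS composite grid
#'   (multiples of 1/3)? Default `TRUE`.
#' @param seed Integer seed.
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(n_patients = 155, n_symptoms = 32,
                              n_visits = 6,
                              cluster_spec = NULL,
                              shift_sd = 0.6, amplitude_sd = 0.15,
                              noise_sd = 0.3,
                              leadlag_pairs = list(),
                              missing_visit_prob = 0,
                              n_complete = NA,
                              ordinal_rounding = TRUE,
                              seed = 1) {
  if (n_symptoms == 32) {
    symptoms <- msas_catalogue()$symptom_id
  } else {
    symptoms <- sprintf("S%02d", seq_len(n_symptoms))
  }
  if (is.null(cluster_spec)) cluster_spec <- default_cluster_spec(symptoms)
  members <- unlist(lapply(cluster_spec, `[[`, "members"))
  if (anyDuplicated(members) || !setequal(members, symptoms)) {
    stop("cluster members must partition the symptom set")
  }
  for (p in leadlag_pairs) {
    if (!all(c("driver", "follower", "lag") %in% names(p))) {
      stop("each lead-lag pair needs driver, follower and lag")
    }
    if (p$lag < 1 || p$lag != round(p$lag)) stop("lags must be integers >= 1")
    if (!p$driver %in% symptoms || !p$follower %in% symptoms) {
      stop("lead-lag pair references an unknown symptom")
    }
    if (p$driver == p$follower) stop("driver and follower must differ")
  }
  followers <- vapply(leadlag_pairs, `[[`, "", "follower")
  drivers <- vapply(leadlag_pairs, `[[`, "", "driver")
  if (anyDuplicated(followers) || any(followers %in% drivers)) {
    stop("followers must be unique and must not themselves drive")
  }
  if (missing_visit_prob < 0 || missing_visit_prob > 1) {
    stop("missing_visit_prob must be in [0, 1]")
  }
  if (is.null(n_complete) || length(n_complete) != 1) n_complete <- NA
  n_complete <- suppressWarnings(as.numeric(n_complete))
  if (!is.na(n_complete) &&
      (n_complete < 0 || n_complete > n_patients)) {
    stop("n_complete must be between 0 and n_patients")
  }
  structure(
    list(n_patients = n_patients, n_symptoms = n_symptoms,
         n_visits = n_visits, symptoms = symptoms,
         cluster_spec = cluster_spec, shift_sd = shift_sd,
         amplitude_sd = amplitude_sd, noise_sd = noise_sd,
         leadlag_pairs = leadlag_pairs,
         missing_visit_prob = missing_visit_prob,
         n_complete = n_complete,
         ordinal_rounding = ordinal_rounding, seed = seed),
    class = "simulation_config")
}

#' Generate a synthetic symptom panel with known ground truth
#'
#' Each symptom's trajectory is its cluster's prototype shape, evaluated on
#' the patient's shifted visit grid (edge-padded), scaled by a patient- and
#' symptom-specific amplitude, plus Gaussian noise, clipped to \[0, 4\] and
#' optionally rounded to the composite-score grid (thirds). Followers in
#' lead-lag pairs are time-delayed copies of their driver's noise-free
#' series plus their own noise. Follow-up visits are dropped with
#' `missing_visit_prob`, or attrition is forced exactly when `n_complete`
#' is set.
#'
#' @param config A [simulation_config()].
#' @return List with `panel` (a [symptom_panel()]) and `truth`
#'   (`cluster_labels`, `roles`, `shifts`, `config`).
#' @export
generate_panel <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  V <- config$n_visits
  S <- config$n_symptoms
  P <- config$n_patients
  syms <- config$symptoms
  pats <- sprintf("P%03d", seq_len(P))

  labels <- integer(S); names(labels) <- syms
  base <- matrix(0, S, V, dimnames = list(syms, NULL))
  for (cl in config$cluster_spec) {
    labels[cl$members] <- cl$cluster_id
    base[cl$members, ] <- matrix(
      prototype_trajectory(cl$shape, 0:(V - 1)),
      nrow = length(cl$members), ncol = V, byrow = TRUE)
  }
  roles <- rep("none", S); names(roles) <- syms
  for (p in config$leadlag_pairs) {
    roles[p$driver] <- "driver"
    roles[p$follower] <- "follower"
  }

  clamp <- function(i) pmin(V, pmax(1, i))
  scores <- array(NA_real_, dim = c(P, S, V),
                  dimnames = list(pats, syms,
                                  paste0("visit_", 0:(V - 1))))
  observed <- matrix(TRUE, P, V, dimnames = list(pats, NULL))
  shifts <- integer(P); names(shifts) <- pats

  withr::with_seed(config$seed, {
    shifts[] <- pmin(2L, pmax(-2L, as.integer(round(
      rnorm(P, 0, config$shift_sd)))))
    for (p in seq_len(P)) {
      idx <- clamp(seq_len(V) - shifts[p])
      amp <- pmax(0.2, rnorm(S, 1, config$amplitude_sd))
      clean <- base[, idx, drop = FALSE] * amp
      for (pr in config$leadlag_pairs) {
        di <- match(pr$driver, syms)
        fi <- match(pr$follower, syms)
        clean[fi, ] <- clean[di, clamp(seq_len(V) - pr$lag)]
      }
      noisy <- clean + matrix(rnorm(S * V, 0, config$noise_sd), S, V)
      noisy <- pmin(4, pmax(0, noisy))
      if (config$ordinal_rounding) noisy <- round(noisy * 3) / 3
      scores[p, , ] <- noisy
    }
    if (!is.na(config$n_complete) && config$n_complete < P) {
      complete <- sample(pats, config$n_complete)
      drop_p <- max(config$missing_visit_prob, 0.15)
      for (p in setdiff(pats, complete)) {
        miss <- runif(V - 1) < drop_p
        if (!any(miss)) miss[sample.int(V - 1, 1)] <- TRUE
        observed[p, which(miss) + 1L] <- FALSE
      }
    } else if (config$missing_visit_prob > 0) {
      for (p in pats) {
        miss <- runif(V - 1) < config$missing_visit_prob
        observed[p, which(miss) + 1L] <- FALSE
      }
    }
  })
  for (p in seq_len(P)) {
    scores[p, , !observed[p, ]] <- NA_real_
  }

  panel <- symptom_panel(scores, observed,
                         if (S == 32) msas_catalogue() else
                           data.frame(symptom_id = syms, label = syms,
                                      stringsAsFactors = FALSE))
  list(panel = panel,
       truth = list(cluster_labels = labels, roles = roles,
                    shifts = shifts, config = config))
}
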