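#' The 32-item MSAS symptom catalogue
#'
#' Reads a symptom catalogue mapping symptom identifiers (`S01`...`S32`) to
#' human-readable labels. The packaged default is the 32-item Memorial
#' Symptom Assessment Scale item list; a custom catalogue file with the same
#' two columns may be supplied to work with other instruments.
#'
#' @param file Path to a CSV with columns `symptom_id` and `label`. Defaults
#'   to the catalogue shipped with the package.
#' @return A data frame with columns `symptom_id` and `label`.
#' @export
#' @examples
#' head(msas_catalogue())
msas_catalogue <- function(file = NULL) {
  if (is.null(file)) {
    file <- system.file("extdata", "msas_catalogue.csv", package = "sympdyn",
                        mustWork = TRUE)
  }
  cat <- utils::read.csv(file, stringsAsFactors = FALSE)
  if (!all(c("symptom_id", "label") %in% names(cat))) {
    stop("catalogue file must have columns 'symptom_id' and 'label'")
  }
  if (anyDuplicated(cat$symptom_id)) stop("duplicated symptom_id in catalogue")
  cat[, c("symptom_id", "label")]
}

#' Composite MSAS item score
#'
#' Scores a symptom assessment as the mean of its frequency, severity and
#' distress ratings. Symptoms not endorsed at a visit (`present = FALSE`)
#' score 0, so that every symptom has a fully defined trajectory.
#'
#' Rating scales follow the instrument's anchors: frequency and severity on
#' 1--4, distress on 0--4. The ranges are configurable for adapted scales.
#'
#' @param present Logical vector; was the symptom endorsed?
#' @param frequency,severity,distress Numeric ratings; must be `NA` wherever
#'   `present` is `FALSE`.
#' @param frequency_range,severity_range,distress_range Length-2 numeric
#'   vectors giving the inclusive admissible range of each rating.
#' @return Numeric vector of scores in \[0, 4\].
#' @export
#' @examples
#' score_item(TRUE, 3, 2, 4)   # 3
#' score_item(FALSE)           # 0
score_item <- function(present, frequency = NA_real_, severity = NA_real_,
                       distress = NA_real_,
                       frequency_range = c(1, 4), severity_range = c(1, 4),
                       distress_range = c(0, 4)) {
  n <- max(length(present), length(frequency), length(severity),
           length(distress))
  present <- rep_len(as.logical(present), n)
  frequency <- rep_len(as.numeric(frequency), n)
  severity <- rep_len(as.numeric(severity), n)
  distress <- rep_len(as.numeric(distress), n)
  if (anyNA(present)) stop("'present' must be TRUE or FALSE, not NA")

  check_rating <- function(x, rng, field) {
    bad_absent <- !present & !is.na(x)
    if (any(bad_absent)) {
      stop(sprintf("'%s' is populated for a non-endorsed symptom", field))
    }
    bad_missing <- present & is.na(x)
    if (any(bad_missing)) {
      stop(sprintf("'%s' is missing for an endorsed symptom", field))
    }
    out <- present & (x < rng[1] | x > rng[2])
    if (any(out, na.rm = TRUE)) {
      stop(sprintf("'%s' outside its ordinal range [%g, %g]",
                   field, rng[1], rng[2]))
    }
  }
  check_rating(frequency, frequency_range, "frequency")
  check_rating(severity, severity_range, "severity")
  check_rating(distress, distress_range, "distress")

  score <- numeric(n)
  score[present] <- (frequency[present] + severity[present] +
                       distress[present]) / 3
  score
}

#' Construct a longitudinal symptom panel
#'
#' A symptom panel holds one score per (patient, symptom, visit) cell on the
#' 0--4 composite scale, plus a per-(patient, visit) observation mask.
#' Visits are an equally spaced index grid `0..n_visits-1`; calendar spacing
#' is deliberately ignored because the DTW band is declared in visit steps.
#'
#' @param scores 3-d numeric array `patients x symptoms x visits` with
#'   dimnames; cells of unobserved visits must be `NA`.
#' @param observed Logical `patients x visits` matrix; defaults to marking a
#'   visit observed when all its symptom scores are non-`NA`.
#' @param symptoms Catalogue data frame (see [msas_catalogue()]); its
#'   `symptom_id` order must match `dimnames(scores)[[2]]`.
#' @return An object of class `symptom_panel`.
#' @export
symptom_panel <- function(scores, observed = NULL, symptoms = NULL) {
  if (!is.array(scores) || length(dim(scores)) != 3) {
    stop("'scores' must be a 3-d array (patients x symptoms x visits)")
  }
  dn <- dimnames(scores)
  if (is.null(dn) || any(vapply(dn, is.null, logical(1)))) {
    stop("'scores' must carry full dimnames")
  }
  if (is.null(observed)) {
    observed <- apply(!is.na(scores), c(1, 3), all)
  }
  observed <- as.matrix(observed)
  if (is.null(symptoms)) {
    symptoms <- data.frame(symptom_id = dn[[2]], label = dn[[2]],
                           stringsAsFactors = FALSE)
  }
  panel <- structure(
    list(scores = scores, observed = observed, symptoms = symptoms),
    class = "symptom_panel")
  validate_panel(panel)
  panel
}

validate_panel <- function(panel) {
  sc <- panel$scores
  ob <- panel$observed
  d <- dim(sc)
  if (!identical(dim(ob), d[c(1, 3)])) {
    stop("'observed' must be patients x visits")
  }
  if (!is.logical(ob) || anyNA(ob)) stop("'observed' must be TRUE/FALSE")
  if (!identical(panel$symptoms$symptom_id, dimnames(sc)[[2]])) {
    stop("symptom catalogue does not match score dimnames")
  }
  for (p in seq_len(d[1])) {
    obs <- ob[p, ]
    if (any(obs) && anyNA(sc[p, , obs])) {
      stop("score undefined at an observed (patient, visit) cell")
    }
  }
  rng <- range(sc, na.rm = TRUE)
  if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 4)) {
    stop("scores must lie in [0, 4]")
  }
  invisible(panel)
}

#' @export
print.symptom_panel <- function(x, ...) {
  d <- dim(x$scores)
  n_complete <- sum(rowSums(x$observed) == d[3])
  cat(sprintf(
    "symptom_panel: %d patients x %d symptoms x %d visits (%d complete)\n",
    d[1], d[2], d[3], n_complete))
  invisible(x)
}

#' Panel accessors
#'
#' @param panel A `symptom_panel`.
#' @return `panel_patients()` / `panel_symptoms()` / `panel_visits()` return
#'   the respective identifier vectors; `panel_scores()` returns the
#'   `symptoms x visits` score matrix of one patient.
#' @name panel-accessors
NULL

#' @rdname panel-accessors
#' @export
panel_patients <- function(panel) dimnames(panel$scores)[[1]]

#' @rdname panel-accessors
#' @export
panel_symptoms <- function(panel) dimnames(panel$scores)[[2]]

#' @rdname panel-accessors
#' @export
panel_visits <- function(panel) dimnames(panel$scores)[[3]]

#' @rdname panel-accessors
#' @param patient_id A single patient identifier.
#' @export
panel_scores <- function(panel, patient_id) {
  if (!patient_id %in% panel_patients(panel)) {
    stop("unknown patient: ", patient_id)
  }
  panel$scores[patient_id, , ]
}

#' Read a symptom panel from tabular data
#'
#' Long layout rows carry `patient_id, symptom_id, visit_index` plus either a
#' precomputed `score` column or the three ratings
#' (`frequency, severity, distress`, optionally `present`); when ratings are
#' given, scores are produced by [score_item()]. Wide layout rows carry
#' `patient_id, symptom_id` plus one `visit_<i>` score column per visit.
#'
#' A (patient, visit) is observed when at least one row mentions it
#' (long layout) or its cells are non-`NA` (wide layout); symptoms without a
#' row at an observed visit score 0 (non-endorsed).
#'
#' @param table A data frame or path to a delimited file (CSV/TSV inferred
#'   from the extension).
#' @param layout `"long"` or `"wide"`.
#' @param symptoms Symptom catalogue data frame; rows with a `symptom_id`
#'   outside the catalogue are an error.
#' @param n_visits Number of visit-grid points (default 6).
#' @return A validated [symptom_panel()].
#' @export
read_panel <- function(table, layout = c("long", "wide"),
                       symptoms = msas_catalogue(), n_visits = 6) {
  layout <- match.arg(layout)
  if (is.character(table)) {
    sep <- if (grepl("\\.tsv$", table, ignore.case = TRUE)) "\t" else ","
    table <- utils::read.csv(table, sep = sep, stringsAsFactors = FALSE)
  }
  table <- as.data.frame(table)
  sym_ids <- symptoms$symptom_id
  check_symptoms <- function(ids) {
    bad <- setdiff(unique(ids), sym_ids)
    if (length(bad)) {
      stop("unknown symptom label(s): ", paste(bad, collapse = ", "),
           "; catalogue: ", paste(sym_ids, collapse = ", "))
    }
  }

  if (layout == "long") {
    need <- c("patient_id", "symptom_id", "visit_index")
    if (!all(need %in% names(table))) {
      stop("long layout needs columns: ", paste(need, collapse = ", "))
    }
    check_symptoms(table$symptom_id)
    if (any(!table$visit_index %in% 0:(n_visits - 1))) {
      stop("visit_index outside the visit grid 0..", n_visits - 1)
    }
    key <- paste(table$patient_id, table$symptom_id, table$visit_index)
    if (anyDuplicated(key)) {
      stop("duplicate (patient, symptom, visit) rows")
    }
    if ("score" %in% names(table)) {
      sc <- as.numeric(table$score)
    } else {
      need_r <- c("frequency", "severity", "distress")
      if (!all(need_r %in% names(table))) {
        stop("long layout needs a 'score' column or the three rating columns")
      }
      present <- if ("present" %in% names(table)) {
        as.logical(table$present)
      } else {
        !is.na(table$frequency)
      }
      sc <- score_item(present, table$frequency, table$severity,
                       table$distress)
    }
    pats <- unique(table$patient_id)
    scores <- array(NA_real_, dim = c(length(pats), length(sym_ids), n_visits),
                    dimnames = list(pats, sym_ids,
                                    paste0("visit_", 0:(n_visits - 1))))
    observed <- matrix(FALSE, length(pats), n_visits,
                       dimnames = list(pats, NULL))
    pi <- match(table$patient_id, pats)
    si <- match(table$symptom_id, sym_ids)
    vi <- table$visit_index + 1L
    observed[cbind(pi, vi)] <- TRUE
    for (p in seq_along(pats)) {
      obs <- observed[p, ]
      scores[p, , obs] <- 0
    }
    scores[cbind(pi, si, vi)] <- sc
  } else {
    vis_cols <- paste0("visit_", 0:(n_visits - 1))
    if (!all(c("patient_id", "symptom_id", vis_cols) %in% names(table))) {
      stop("wide layout needs columns patient_id, symptom_id, ",
           paste(vis_cols, collapse = ", "))
    }
    check_symptoms(table$symptom_id)
    key <- paste(table$patient_id, table$symptom_id)
    if (anyDuplicated(key)) stop("duplicate (patient, symptom) rows")
    pats <- unique(table$patient_id)
    scores <- array(NA_real_, dim = c(length(pats), length(sym_ids), n_visits),
                    dimnames = list(pats, sym_ids, vis_cols))
    pi <- match(table$patient_id, pats)
    si <- match(table$symptom_id, sym_ids)
    for (v in seq_len(n_visits)) {
      scores[cbind(pi, si, v)] <- as.numeric(table[[vis_cols[v]]])
    }
    observed <- matrix(FALSE, length(pats), n_visits,
                       dimnames = list(pats, NULL))
    n_sym <- length(sym_ids)
    for (p in seq_along(pats)) {
      pm <- matrix(scores[p, , ], nrow = n_sym)
      filled <- colSums(!is.na(pm))
      if (any(filled > 0 & filled < n_sym)) {
        stop("wide layout: visit partially NA for patient ", pats[p])
      }
      observed[p, ] <- filled == n_sym
    }
  }
  symptom_panel(scores, observed, symptoms)
}

#' Serialize a symptom panel to tabular form
#'
#' Inverse of [read_panel()]: `read_panel(write_panel(p, layout = l), l)`
#' reproduces `p` for both layouts.
#'
#' @param panel A `symptom_panel`.
#' @param path Optional file path; when given, a CSV is written.
#' @param layout `"long"` or `"wide"`.
#' @return The data frame (invisibly when `path` is given).
#' @export
write_panel <- function(panel, path = NULL, layout = c("long", "wide")) {
  layout <- match.arg(layout)
  sc <- panel$scores
  d <- dim(sc)
  pats <- panel_patients(panel)
  syms <- panel_symptoms(panel)
  if (layout == "long") {
    rows <- vector("list", d[1])
    for (p in seq_len(d[1])) {
      obs <- which(panel$observed[p, ])
      if (!length(obs)) next
      g <- expand.grid(symptom_id = syms, visit_index = obs - 1L,
                       stringsAsFactors = FALSE)
      g$patient_id <- pats[p]
      g$score <- as.vector(sc[p, , obs])
      rows[[p]] <- g[, c("patient_id", "symptom_id", "visit_index", "score")]
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
  } else {
    g <- expand.grid(symptom_id = syms, patient_id = pats,
                     stringsAsFactors = FALSE)
    out <- data.frame(patient_id = g$patient_id, symptom_id = g$symptom_id,
                      stringsAsFactors = FALSE)
    for (v in seq_len(d[3])) {
      col <- sc[cbind(match(out$patient_id, pats),
                      match(out$symptom_id, syms),
                      v)]
      out[[paste0("visit_", v - 1L)]] <- col
    }
  }
  if (!is.null(path)) {
    utils::write.csv(out, path, row.names = FALSE)
    return(invisible(out))
  }
  out
}

#' Keep only patients observed at every visit
#'
#' Retains exactly the patients whose every visit is observed (the study
#' design excludes participants completing five or fewer of the six
#' assessments); patient order is preserved and the operation is idempotent.
#'
#' @param panel A `symptom_panel`.
#' @return The filtered panel.
#' @export
filter_complete <- function(panel) {
  keep <- rowSums(panel$observed) == ncol(panel$observed)
  if (!any(keep)) stop("no complete cases: every patient has missing visits")
  if (all(keep)) return(panel)
  symptom_panel(panel$scores[keep, , , drop = FALSE],
                panel$observed[keep, , drop = FALSE],
                panel$symptoms)
}
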