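# Independent brute-force oracle: enumerates every admissible warping path
# from (1,1) to (N,M) with symmetric2 weights (first cell weight 1, diagonal
# steps 2, axis steps 1) and returns the minimum cumulative cost. Written
# before and independently of the dynamic program it checks; branch-and-bound
# pruning only discards paths already costlier than the incumbent.
enum_dtw <- function(a, b, width = Inf, forward = FALSE, squared = FALSE) {
  n <- length(a)
  m <- length(b)
  cost <- function(i, j) {
    d <- abs(a[i] - b[j])
    if (squared) d^2 else d
  }
  in_band <- function(i, j) {
    if (forward) (j - i) >= 0 && (j - i) <= width else abs(i - j) <= width
  }
  best <- Inf
  rec <- function(i, j, acc) {
    if (acc >= best) return(invisible())
    if (i == n && j == m) {
      best <<- acc
      return(invisible())
    }
    if (i < n && j < m && in_band(i + 1, j + 1)) {
      rec(i + 1, j + 1, acc + 2 * cost(i + 1, j + 1))
    }
    if (i < n && in_band(i + 1, j)) rec(i + 1, j, acc + cost(i + 1, j))
    if (j < m && in_band(i, j + 1)) rec(i, j + 1, acc + cost(i, j + 1))
    invisible()
  }
  if (!in_band(1, 1) || !in_band(n, m)) return(Inf)
  rec(1, 1, cost(1, 1))
  best
}

# Tiny catalogue + panel builders used across test files
toy_catalogue <- function(n = 3) {
  ids <- sprintf("S%02d", seq_len(n))
  data.frame(symptom_id = ids, label = paste("symptom", ids),
             stringsAsFactors = FALSE)
}

toy_panel <- function(scores_by_patient, observed = NULL) {
  # scores_by_patient: named list of symptoms x visits matrices
  pats <- names(scores_by_patient)
  n_sym <- nrow(scores_by_patient[[1]])
  n_vis <- ncol(scores_by_patient[[1]])
  cat <- toy_catalogue(n_sym)
  arr <- array(NA_real_, dim = c(length(pats), n_sym, n_vis),
               dimnames = list(pats, cat$symptom_id,
                               paste0("visit_", seq_len(n_vis) - 1)))
  for (p in pats) arr[p, , ] <- scores_by_patient[[p]]
  symptom_panel(arr, observed, cat)
}

# low-noise study conditions used by the recovery/stability properties
lownoise_config <- function(n_patients, seed, cluster_spec = NULL,
                            leadlag_pairs = list()) {
  simulation_config(n_patients = n_patients, seed = seed,
                    cluster_spec = cluster_spec,
                    noise_sd = 0.15, shift_sd = 0.3,
                    leadlag_pairs = leadlag_pairs)
}
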