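#' Parameters of the surrogate 5-state HMM caller
#'
#' A homogeneous-transition hidden Markov model over copy states 0..4 with
#' Gaussian LRR emissions, standing in for array CNV callers such as
#' PennCNV. Default emission means are the damped theoretical LRR values
#' (zero-copy floor -1, then -0.5, 0, 0.5*log2(3/2), 0.5), all emission
#' sds 0.15. The transition matrix keeps the current state with
#' probability `stay_prob` and splits the remainder evenly over the other
#' four states; `stay_prob` controls the evidence (in nats,
#' `2*log((1-stay_prob)/(4*stay_prob))` for entering and leaving a
#' segment) a CNV must accumulate to be called. The default 0.99999 makes
#' 1-3-probe deletions essentially uncallable while deletions of 8+
#' probes are recovered with high probability, mirroring observed caller
#' behaviour; probe spacing is uniform so no distance-dependent
#' transitions are modelled.
#'
#' @param state_means emission means for states 0..4 (log2 units).
#' @param state_sds emission sds, all > 0.
#' @param stay_prob per-probe probability of remaining in the current
#'   state, in (0, 1).
#' @param cnv_prior initial probability on each non-reference state.
#' @return An object of class `"hmm_params"`.
#' @export
hmm_params <- function(state_means = c(-1, -0.5, 0, 0.5 * log2(3 / 2), 0.5),
                       state_sds = rep(0.15, 5),
                       stay_prob = 0.99999,
                       cnv_prior = 1e-4) {
  stopifnot(length(state_means) == 5L, length(state_sds) == 5L,
            all(state_sds > 0), stay_prob > 0, stay_prob < 1,
            cnv_prior > 0, 4 * cnv_prior < 1)
  structure(list(state_means = state_means, state_sds = state_sds,
                 stay_prob = stay_prob, cnv_prior = cnv_prior),
            class = "hmm_params")
}

.hmm_logs <- function(params) {
  off <- (1 - params$stay_prob) / 4
  A <- matrix(off, 5L, 5L)
  diag(A) <- params$stay_prob
  init <- rep(params$cnv_prior, 5L)
  init[3L] <- 1 - 4 * params$cnv_prior
  list(log_trans = log(A), log_init = log(init))
}

.segments_from_path <- function(path) {
  r <- rle(path)
  end <- cumsum(r$lengths)
  start <- end - r$lengths + 1L
  keep <- r$values != 2L
  data.frame(start = start[keep], end = end[keep],
             state = r$values[keep])
}

#' Viterbi segmentation of one LRR vector
#'
#' Decodes the most probable copy-state path under the surrogate HMM and
#' emits maximal runs of non-reference states as call segments (the
#' reference state 2 is implicit). Deterministic given input and
#' parameters.
#'
#' @param lrr numeric vector of observed LRR values (finite).
#' @param params an [hmm_params()].
#' @return Data frame with columns `start`, `end` (1-based inclusive probe
#'   indices) and `state` (0, 1, 3 or 4); zero rows if no CNV is called.
#' @export
viterbi_segment <- function(lrr, params = hmm_params()) {
  stopifnot(inherits(params, "hmm_params"))
  if (length(lrr) == 0L) stop("empty LRR vector")
  lg <- .hmm_logs(params)
  path <- viterbi_paths_cpp(matrix(as.numeric(lrr), nrow = 1L),
                            params$state_means, params$state_sds,
                            lg$log_init, lg$log_trans)[1L, ]
  .segments_from_path(path)
}

#' Call CNVs for every subject in an LRR matrix
#'
#' @param lrr subjects x probes numeric matrix (rows named by subject).
#' @param params an [hmm_params()].
#' @return Data frame with columns `subject`, `start`, `end`, `state` —
#'   one row per called non-reference segment.
#' @export
call_cnvs <- function(lrr, params = hmm_params()) {
  stopifnot(is.matrix(lrr), ncol(lrr) >= 1L)
  lg <- .hmm_logs(params)
  paths <- viterbi_paths_cpp(lrr, params$state_means, params$state_sds,
                             lg$log_init, lg$log_trans)
  subjects <- rownames(lrr) %||% paste0("subject_", seq_len(nrow(lrr)))
  segs <- lapply(seq_len(nrow(lrr)), function(i) {
    s <- .segments_from_path(paths[i, ])
    if (nrow(s)) cbind(subject = subjects[i], s, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, segs)
  if (is.null(out))
    out <- data.frame(subject = character(0), start = integer(0),
                      end = integer(0), state = integer(0))
  rownames(out) <- NULL
  out
}

#' Recovery rate of a true CNV region from call segments
#'
#' A carrier counts as recovered when at least one of its called segments
#' overlaps the true region by one or more probes with a called state on
#' the same side of 2 as the true state (a deletion call cannot recover a
#' duplication, and vice versa).
#'
#' @param calls data frame of call segments as from [call_cnvs()].
#' @param region true region: list with `start`, `end`, `state`,
#'   `carriers` (as in a [simulate_cohort()] result).
#' @return Recovered carriers / total carriers, in \[0, 1\].
#' @export
recovery_rate <- function(calls, region) {
  stopifnot(!is.null(region), length(region$carriers) > 0)
  dir <- sign(region$state - 2)
  ok <- calls$subject %in% region$carriers &
    sign(calls$state - 2) == dir &
    calls$start <= region$end & calls$end >= region$start
  length(unique(calls$subject[ok])) / length(region$carriers)
}

#' Recovery rate as a function of CNV size
#'
#' For each size, simulates a fresh cohort ([simulate_cohort()]), runs the
#' Viterbi caller on the carriers, and scores recovery. Only carrier rows
#' are decoded: recovery is a property of carriers alone.
#'
#' @param sizes integer CNV sizes in probes.
#' @param cnv_type `"deletion"` or `"duplication"`.
#' @param params an [hmm_params()].
#' @param n_subjects,n_probes,n_carriers,model cohort settings passed to
#'   [simulate_cohort()]. Smaller (windowed) probe grids than the
#'   reference 10000 give the same recovery up to boundary effects and
#'   run much faster.
#' @param n_cohorts independent cohort replicates averaged per size.
#' @return Data frame with columns `size` and `recovery`.
#' @export
recovery_curve <- function(sizes, cnv_type = c("deletion", "duplication"),
                           params = hmm_params(), n_subjects = 1000,
                           n_probes = 10000, n_carriers = 200,
                           model = lrr_model("array"), n_cohorts = 1) {
  cnv_type <- match.arg(cnv_type)
  stopifnot(all(sizes >= 1), all(sizes <= n_probes))
  rec <- vapply(sizes, function(sz) {
    mean(vapply(seq_len(n_cohorts), function(rep) {
      ch <- simulate_cohort(sz, cnv_type, n_subjects, n_probes,
                            n_carriers, model)
      calls <- call_cnvs(ch$lrr[ch$region$carriers, , drop = FALSE], params)
      recovery_rate(calls, ch$region)
    }, numeric(1)))
  }, numeric(1))
  data.frame(size = sizes, recovery = rec)
}

#' End-to-end power of association on called CNVs, by size
#'
#' The full pipeline, replicated: simulate a cohort, call every subject
#' with the HMM, build the called-carrier indicator (a subject is an
#' observed carrier when any of its called segments overlaps the true
#' region in the right direction), simulate the phenotype on the true
#' carriers, and run the OLS slope test. Power per size is the fraction
#' of significant replicates. Cross-checks [compose_power_vs_size()].
#'
#' @inheritParams recovery_curve
#' @param trait a [trait_model()].
#' @param config a [power_config()]; `n_subjects` is taken from the cohort
#'   arguments, `n_replicates` counts cohort replicates per size.
#' @return Data frame with columns `size`, `power`, `mc_se`.
#' @export
end_to_end_power <- function(sizes, cnv_type = c("deletion", "duplication"),
                             trait = trait_model(), config = power_config(),
                             params = hmm_params(), n_subjects = 1000,
                             n_probes = 500, n_carriers = 200,
                             model = lrr_model("array")) {
  cnv_type <- match.arg(cnv_type)
  if (!is.null(config$seed)) set.seed(config$seed)
  freq <- n_carriers / n_subjects
  reps <- config$n_replicates
  out <- lapply(sizes, function(sz) {
    hits <- 0L
    for (b in seq_len(reps)) {
      ch <- simulate_cohort(sz, cnv_type, n_subjects, n_probes,
                            n_carriers, model)
      calls <- call_cnvs(ch$lrr, params)
      dir <- sign(ch$region$state - 2)
      ok <- sign(calls$state - 2) == dir &
        calls$start <= ch$region$end & calls$end >= ch$region$start
      observed <- rownames(ch$lrr) %in% unique(calls$subject[ok])
      x_true <- rownames(ch$lrr) %in% ch$region$carriers
      y <- simulate_phenotype(as.numeric(x_true), trait, freq)
      if (slope_test(y, as.numeric(observed), config$alpha)$significant)
        hits <- hits + 1L
    }
    est <- power_estimate(hits, reps)
    data.frame(size = sz, power = est$power, mc_se = est$mc_se)
  })
  do.call(rbind, out)
}
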