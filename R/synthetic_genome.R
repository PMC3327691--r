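#' Simulate a probe-grid LRR cohort with an embedded CNV
#'
#' Generates a synthetic SNP-array cohort: a single chromosome of equally
#' spaced probes (1 kb apart), an integer-copy CNV region centred on the
#' grid and carried by a fixed number of subjects, and an observed LRR
#' matrix with independent Gaussian noise. Carrier probes inside the
#' region are centred at the damped one-copy mean (-0.5, deletions) or
#' three-copy mean (0.5 * log2(3/2), duplications); every other cell is
#' centred at 0. Defaults match the reference design: 1000 subjects,
#' 10000 probes, 200 carriers, noise sd 0.15.
#'
#' @param cnv_size CNV length in probes (0 for a pure-noise cohort;
#'   1 to 25 at reference scale).
#' @param cnv_type `"deletion"` (true state 1) or `"duplication"` (state 3).
#' @param n_subjects,n_probes,n_carriers cohort dimensions.
#' @param model an [lrr_model()] supplying the damped means and noise sd.
#' @return A list of class `"cnv_cohort"`:
#'   \describe{
#'     \item{probes}{data frame `name`, `chr`, `position` (1-based bp,
#'       uniform 1 kb spacing).}
#'     \item{region}{list `start`, `end` (1-based inclusive probe
#'       indices), `state`, `carriers` (subject ids); `NULL` when
#'       `cnv_size = 0`.}
#'     \item{lrr}{`n_subjects` x `n_probes` numeric matrix, rows named by
#'       subject.}
#'   }
#' Uses R's global RNG; with a fixed seed the cohort is bit-reproducible.
#' @export
simulate_cohort <- function(cnv_size, cnv_type = c("deletion", "duplication"),
                            n_subjects = 1000, n_probes = 10000,
                            n_carriers = 200, model = lrr_model("array")) {
  cnv_type <- match.arg(cnv_type)
  stopifnot(cnv_size >= 0, cnv_size <= n_probes, n_carriers <= n_subjects,
            n_probes >= 1, n_subjects >= 1)
  probes <- data.frame(
    name = paste0("probe_", seq_len(n_probes)),
    chr = "1",
    position = seq_len(n_probes) * 1000L,
    stringsAsFactors = FALSE
  )
  subjects <- paste0("subject_", seq_len(n_subjects))
  lrr <- matrix(rnorm(n_subjects * n_probes, 0, model$noise_sd),
                n_subjects, n_probes,
                dimnames = list(subjects, probes$name))
  region <- NULL
  if (cnv_size > 0) {
    start <- floor((n_probes - cnv_size) / 2) + 1L
    end <- start + as.integer(cnv_size) - 1L
    state <- if (cnv_type == "deletion") 1L else 3L
    carriers <- sort(sample.int(n_subjects, n_carriers))
    shift <- theoretical_lrr(state, model)
    lrr[carriers, start:end] <- lrr[carriers, start:end] + shift
    region <- list(start = start, end = end, state = state,
                   carriers = subjects[carriers])
  }
  structure(list(probes = probes, region = region, lrr = lrr),
            class = "cnv_cohort")
}

#' @export
print.cnv_cohort <- function(x, ...) {
  cat(sprintf("<cnv_cohort> %d subjects x %d probes\n",
              nrow(x$lrr), ncol(x$lrr)))
  if (!is.null(x$region))
    cat(sprintf("  CNV state %d at probes %d-%d (%d carriers)\n",
                x$region$state, x$region$start, x$region$end,
                length(x$region$carriers)))
  invisible(x)
}

#' Write a cohort as a PennCNV-style signal-intensity file
#'
#' Tab-delimited text with header
#' `Name  Chr  Position  <subject>.Log R Ratio ...` — one LRR column per
#' subject, one row per probe. Values are written with 6 decimals, so a
#' write/read round trip preserves them to 1e-6.
#'
#' @param cohort a `"cnv_cohort"` (or any list with `probes` and `lrr`).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_signal_file <- function(cohort, path) {
  probes <- cohort$probes
  lrr <- cohort$lrr
  stopifnot(is.matrix(lrr), nrow(probes) == ncol(lrr))
  subjects <- rownames(lrr) %||% paste0("subject_", seq_len(nrow(lrr)))
  header <- c("Name", "Chr", "Position",
              paste0(subjects, ".Log R Ratio"))
  body <- cbind(probes$name, probes$chr, probes$position,
                t(formatC(lrr, digits = 6, format = "f")))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(header, collapse = "\t"), con)
  writeLines(apply(body, 1L, paste, collapse = "\t"), con)
  invisible(path)
}

#' Read a PennCNV-style signal-intensity file
#'
#' Parses the tab-delimited format written by [write_signal_file()]
#' (also accepts single-subject PennCNV export files). Malformed headers,
#' non-numeric LRR values and non-increasing positions raise errors that
#' name the offending line.
#'
#' @param path input file path.
#' @return A list with `probes` (data frame `name`, `chr`, `position`) and
#'   `lrr` (subjects x probes matrix, rows named from the header).
#' @export
read_signal_file <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 1L) stop("empty signal file: ", path)
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  if (length(header) < 4L ||
      !identical(header[1:3], c("Name", "Chr", "Position")))
    stop("malformed header at line 1: expected 'Name\\tChr\\tPosition\\t",
         "<subject>.Log R Ratio ...'")
  subjects <- sub("\\.Log R Ratio$", "", header[-(1:3)])
  n_col <- length(header)
  rows <- strsplit(lines[-1L], "\t", fixed = TRUE)
  bad <- which(lengths(rows) != n_col)
  if (length(bad))
    stop("line ", bad[1L] + 1L, ": expected ", n_col, " fields, found ",
         lengths(rows)[bad[1L]])
  m <- do.call(rbind, rows)
  position <- suppressWarnings(as.numeric(m[, 3L]))
  if (anyNA(position))
    stop("line ", which(is.na(position))[1L] + 1L, ": non-numeric Position")
  if (any(diff(position) <= 0))
    stop("line ", which(diff(position) <= 0)[1L] + 2L,
         ": positions not strictly increasing")
  vals <- suppressWarnings(
    matrix(as.numeric(m[, -(1:3), drop = FALSE]), nrow = nrow(m))
  )
  if (anyNA(vals))
    stop("line ", which(rowSums(is.na(vals)) > 0)[1L] + 1L,
         ": non-numeric Log R Ratio value")
  probes <- data.frame(name = m[, 1L], chr = m[, 2L], position = position,
                       stringsAsFactors = FALSE)
  lrr <- t(vals)
  dimnames(lrr) <- list(subjects, probes$name)
  list(probes = probes, lrr = lrr)
}
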