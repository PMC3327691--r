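#' Default experiment configurations
#'
#' Reference defaults for every runnable experiment: 1000 subjects, 10000
#' replicates, alpha 0.05, variant allele frequency 0.1, array LRR preset
#' (damping 0.5, noise sd 0.15), 200 carriers of 1000 subjects on a
#' 10000-probe grid. A reduced `smoke = TRUE` profile (500 replicates,
#' windowed probe grid) is provided for quick runs.
#'
#' @param name experiment name: one of `"table1"`, `"table2"`,
#'   `"contour"`, `"power_curve"`, `"lrr_power"`, `"recovery_curve"`,
#'   `"power_vs_size"`.
#' @param smoke use the reduced-replicate profile.
#' @return A named list of parameters.
#' @export
experiment_defaults <- function(name, smoke = FALSE) {
  base <- list(
    name = name, seed = 1L, q = 0.1,
    nu_n = c(0, 0.2, 0.5, 0.7, 0.9), nu_p = c(0, 0.05, 0.10),
    target_sd = 0.15,
    freq = 0.2, beta = 2.5, var_y = 100,
    n_subjects = 1000L, n_replicates = if (smoke) 500L else 10000L,
    alpha = 0.05,
    n_probes = if (smoke) 1000L else 10000L, n_carriers = 200L,
    sizes = 1:25, nu_n_grid = seq(0, 1, by = if (smoke) 0.05 else 0.01),
    outdir = "."
  )
  base
}

.known_experiments <- c("table1", "table2", "contour", "power_curve",
                        "lrr_power", "recovery_curve", "power_vs_size")

.write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run a named experiment and write its result tables
#'
#' Executes one of the package's reference computations from a config
#' (a named list, or a path to a YAML file with the same keys), writes
#' tab-separated result tables plus a JSON provenance record (full
#' merged config and package version) to the output directory, and
#' returns the results. Identical configs produce byte-identical output
#' files.
#'
#' Experiments: `table1`/`table2` — sd(Delta) grids for the
#' single-variant and multiallelic locus; `contour` — error-rate pairs
#' with sd(Delta) equal to the LRR noise sd; `power_curve` — simulated
#' power over false-negative rates; `lrr_power` — single-locus LRR power
#' for deletions and duplications; `recovery_curve` — HMM recovery by
#' CNV size; `power_vs_size` — the composed call-power curve with the
#' flat LRR reference lines.
#'
#' @param config named list (must contain `name`) or YAML file path;
#'   missing keys are filled from [experiment_defaults()].
#' @param smoke use reduced-replicate defaults for unset keys.
#' @return List with `result` (data frame or list of data frames),
#'   `files` (paths written) and `config` (merged), invisibly.
#' @export
run_experiment <- function(config, smoke = FALSE) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config), !is.null(config$name))
  if (!config$name %in% .known_experiments)
    stop("unknown experiment: ", config$name, " (known: ",
         paste(.known_experiments, collapse = ", "), ")")
  cfg <- modifyList(experiment_defaults(config$name, smoke), config)
  if (!dir.exists(cfg$outdir) &&
      !dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", cfg$outdir)
  set.seed(cfg$seed)
  trait <- trait_model(cfg$beta, cfg$var_y)
  pcfg <- power_config(cfg$n_subjects, cfg$n_replicates, cfg$alpha)
  out_path <- function(stem) file.path(cfg$outdir,
                                       paste0(cfg$name, "_", stem, ".tsv"))
  files <- character(0)

  result <- switch(cfg$name,
    table1 = {
      tab <- sd_delta_table(locus_model("deletion", q = cfg$q),
                            cfg$nu_n, cfg$nu_p)
      df <- data.frame(nu_n = cfg$nu_n, tab, check.names = FALSE)
      files <- .write_tsv(df, out_path("sd_delta"))
      tab
    },
    table2 = {
      tab <- sd_delta_table(locus_model("multiallelic", q = cfg$q),
                            cfg$nu_n, cfg$nu_p)
      df <- data.frame(nu_n = cfg$nu_n, tab, check.names = FALSE)
      files <- .write_tsv(df, out_path("sd_delta"))
      tab
    },
    contour = {
      dfs <- lapply(c("deletion", "multiallelic"), function(kind) {
        cc <- equivalence_contour(locus_model(kind, q = cfg$q),
                                  cfg$target_sd)
        cbind(locus = kind, cc)
      })
      df <- do.call(rbind, dfs)
      files <- .write_tsv(df, out_path("rates"))
      df
    },
    power_curve = {
      rows <- lapply(cfg$nu_n_grid, function(nn) {
        est <- estimate_power_calls(cfg$freq, error_rates(nn, 0),
                                    trait, pcfg)
        data.frame(nu_n = nn, power = est$power, mc_se = est$mc_se)
      })
      df <- do.call(rbind, rows)
      files <- .write_tsv(df, out_path(paste0("freq", cfg$freq)))
      df
    },
    lrr_power = {
      rows <- lapply(c("deletion", "duplication"), function(tp) {
        est <- estimate_power_lrr(cfg$freq, tp, lrr_model("array"),
                                  trait, pcfg)
        data.frame(cnv_type = tp, power = est$power, mc_se = est$mc_se)
      })
      df <- do.call(rbind, rows)
      files <- .write_tsv(df, out_path("power"))
      df
    },
    recovery_curve = {
      dfs <- lapply(c("deletion", "duplication"), function(tp) {
        rc <- recovery_curve(cfg$sizes, tp, hmm_params(),
                             cfg$n_subjects, cfg$n_probes, cfg$n_carriers)
        cbind(cnv_type = tp, rc)
      })
      df <- do.call(rbind, dfs)
      files <- .write_tsv(df, out_path("by_size"))
      df
    },
    power_vs_size = {
      pw_grid <- seq(0, 1, by = 0.05)
      base_r2 <- explained_r2(trait, cfg$freq)
      pw <- data.frame(
        nu_n = pw_grid,
        power = vapply(pw_grid, function(nn) {
          analytic_power(call_attenuation(cfg$freq, nn), base_r2,
                         cfg$n_subjects, cfg$alpha)
        }, numeric(1))
      )
      dfs <- lapply(c("deletion", "duplication"), function(tp) {
        rc <- recovery_curve(cfg$sizes, tp, hmm_params(),
                             cfg$n_subjects, cfg$n_probes, cfg$n_carriers)
        comp <- compose_power_vs_size(rc, pw)
        lrr <- estimate_power_lrr(cfg$freq, tp, lrr_model("array"),
                                  trait, pcfg)
        cbind(cnv_type = tp, comp, recovery = rc$recovery,
              lrr_power = lrr$power)
      })
      df <- do.call(rbind, dfs)
      files <- .write_tsv(df, out_path("composed"))
      df
    }
  )

  prov <- file.path(cfg$outdir, paste0(cfg$name, "_provenance.json"))
  prov_cfg <- cfg[setdiff(names(cfg), "outdir")] # record parameters, not paths
  jsonlite::write_json(
    list(config = prov_cfg[order(names(prov_cfg))],
         package = "cnvpower",
         version = as.character(packageVersion("cnvpower"))),
    prov, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  files <- c(files, prov)
  invisible(list(result = result, files = files, config = cfg))
}
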