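default_config <- function() {
  list(stages = c("simulate", "correct", "hist", "hmm", "kinetics"),
       fixture = "IC2", n_traces = 100, seed = 1,
       beta = "auto", gamma = "auto", k = "auto", n_states = 3,
       phys_variant = "default", duration = NULL,
       traces = NULL, out_dir = "pipeline_out")
}

validate_config <- function(config) {
  cfg <- modifyList(default_config(), config)
  known <- c("simulate", "correct", "hist", "hmm", "kinetics")
  stop_if_not(all(cfg$stages %in% known),
              paste("unknown stage(s):",
                    paste(setdiff(cfg$stages, known), collapse = ", ")))
  stop_if_not(all(order(match(cfg$stages, known)) == seq_along(cfg$stages)),
              "stages must appear in pipeline order")
  if (!"simulate" %in% cfg$stages) {
    stop_if_not(!is.null(cfg$traces), "without a simulate stage, 'traces' must point to a TSV")
    stop_if_not(file.exists(cfg$traces) &&
                  file.exists(paste0(cfg$traces, ".meta.json")),
                paste("input trace file missing:", cfg$traces))
  }
  cfg
}

write_json_artifact <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE, force = TRUE)
  path
}

#' Run the end-to-end analysis pipeline
#'
#' Orchestrates simulate -> correct -> histogram -> HMM -> kinetics over a
#' packaged fixture (or an existing trace TSV), writing every stage's
#' artifact plus a manifest with input hashes so silent changes are
#' detectable.  Deterministic given the config seeds: re-running with the
#' same config reproduces byte-identical numeric outputs.
#'
#' @param config a named list (or path to a YAML file) with entries
#'   `stages`, `fixture`, `n_traces`, `seed`, `beta`/`gamma`
#'   (`"auto"` or numeric), `k` (`"auto"` or 1-3), `n_states`,
#'   `phys_variant`, `duration`, `traces` (input TSV when not
#'   simulating) and `out_dir`.
#' @return Invisibly, a list with the stage results (`traces`, `fret`,
#'   `hist`, `mixture`, `hmm`, `paths`, `rates`) and the manifest.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- validate_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  artifacts <- character(0)
  res <- list()

  if ("simulate" %in% cfg$stages) {
    traces <- simulate_traces(fixture = cfg$fixture, n_traces = cfg$n_traces,
                              seed = cfg$seed, duration = cfg$duration,
                              phys_variant = cfg$phys_variant)
    tsv <- file.path(cfg$out_dir, "traces.tsv")
    write_traces(traces, tsv)
    artifacts <- c(artifacts, tsv, paste0(tsv, ".meta.json"))
  } else {
    traces <- read_traces(cfg$traces)
  }
  res$traces <- traces

  if ("correct" %in% cfg$stages) {
    kept <- filter_traces(traces)
    traces2 <- subtract_direct_excitation(kept$traces)
    beta <- cfg$beta
    if (identical(beta, "auto")) {
      donly <- Filter(function(tr) !tr$acceptor_present, traces)
      beta <- if (length(donly)) estimate_beta(donly)$beta else 0.08
    }
    gamma <- cfg$gamma
    if (identical(gamma, "auto")) {
      gamma <- tryCatch(estimate_gamma(traces2)$gamma,
                        error = function(e) NA_real_)
    }
    params <- correction_params(beta = beta, gamma = gamma)
    fret <- lapply(traces2, compute_fret, params = params)
    res$fret <- fret
    res$correction <- list(beta = beta, gamma = gamma,
                           filter_report = kept$report)
    corr_json <- file.path(cfg$out_dir, "correction.json")
    write_json_artifact(res$correction, corr_json)
    fret_tab <- do.call(rbind, lapply(fret, function(f)
      data.frame(trace_id = f$trace_id, frame = seq_along(f$time),
                 time_s = f$time, e_fret = f$e_fret, masked = f$masked)))
    fret_tsv <- file.path(cfg$out_dir, "corrected.tsv")
    write.table(fret_tab, fret_tsv, sep = "\t", quote = FALSE,
                row.names = FALSE)
    artifacts <- c(artifacts, corr_json, fret_tsv)
  }

  if ("hist" %in% cfg$stages) {
    vals <- unlist(lapply(res$fret, block_average))
    h <- build_histogram(vals, condition = cfg$fixture,
                         n_traces = length(res$fret))
    res$hist <- h
    mx <- if (identical(cfg$k, "auto")) select_k(h, seed = cfg$seed)$fit
          else fit_mixture(h, cfg$k, seed = cfg$seed)
    res$mixture <- mx
    h_tsv <- file.path(cfg$out_dir, "histogram.tsv")
    write.table(data.frame(bin_lo = head(h$bin_edges, -1),
                           bin_hi = tail(h$bin_edges, -1),
                           count = h$counts),
                h_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
    mx_json <- file.path(cfg$out_dir, "mixture.json")
    write_json_artifact(list(k = mx$k, components = mx$components,
                             bic = mx$bic, chisq_red = mx$chisq_red),
                        mx_json)
    artifacts <- c(artifacts, h_tsv, mx_json)
  }

  if ("hmm" %in% cfg$stages) {
    model <- fit_hmm(res$fret, n_states = cfg$n_states, seed = cfg$seed)
    paths <- lapply(res$fret, function(f) viterbi(model, f))
    res$hmm <- model
    res$paths <- paths
    model_json <- file.path(cfg$out_dir, "hmm.json")
    write_json_artifact(list(means = model$means, sds = model$sds,
                             transition_matrix = model$transition_matrix,
                             initial_probs = model$initial_probs,
                             log_likelihood = model$log_likelihood),
                        model_json)
    path_tab <- do.call(rbind, lapply(paths, function(p)
      if (length(p$states))
        data.frame(trace_id = p$trace_id, frame = seq_along(p$states),
                   state = p$states)))
    paths_tsv <- file.path(cfg$out_dir, "paths.tsv")
    write.table(path_tab, paths_tsv, sep = "\t", quote = FALSE,
                row.names = FALSE)
    artifacts <- c(artifacts, model_json, paths_tsv)
  }

  if ("kinetics" %in% cfg$stages) {
    K <- res$hmm$n_states
    rate_tab <- rates_from_model(res$hmm)
    dwell_rates <- lapply(seq_len(K), function(s) {
      ds <- extract_dwells(res$paths, s, n_states = K,
                           condition = cfg$fixture)
      tryCatch(c(state = s, rate_from_dwells(ds)[c("rate", "se", "n")]),
               error = function(e) list(state = s, rate = NA, se = NA,
                                        n = length(ds$dwells)))
    })
    res$rates <- list(model_rates = rate_tab, dwell_rates = dwell_rates)
    rates_json <- file.path(cfg$out_dir, "rates.json")
    write_json_artifact(res$rates, rates_json)
    artifacts <- c(artifacts, rates_json)
  }

  manifest <- list(
    config = cfg[setdiff(names(cfg), "out_dir")],
    package_version = as.character(utils::packageVersion("scrunchFRET")),
    artifacts = lapply(setNames(nm = basename(artifacts)), function(b)
      unname(tools::md5sum(file.path(cfg$out_dir, b)))))
  write_json_artifact(manifest, file.path(cfg$out_dir, "manifest.json"))
  res$manifest <- manifest
  invisible(res)
}
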