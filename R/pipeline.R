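#' Pipeline configuration
#'
#' @param manifest path to the manifest CSV (see [read_manifest()]).
#' @param output_dir directory for all result artifacts (created if
#'   missing).
#' @param calibration a [calibration_set], or a path to a calibration JSON,
#'   or `NULL` for the package defaults.
#' @param thresholds QC thresholds, see [qc_thresholds()].
#' @param amp_window,offset_window curve-summary lag windows (s).
#' @param bins_per_stage,max_lag correlator grid.
#' @param p_primary,p_secondary strict network thresholds.
#' @param negative_pair manifest `pair` label identifying negative-control
#'   measurements.
#' @param n_prebleach FRAP pre-bleach frame count.
#' @param seed integer seed recorded in outputs (the analysis itself is
#'   deterministic).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(manifest, output_dir,
                            calibration = NULL,
                            thresholds = qc_thresholds(),
                            amp_window = c(25.6e-6, 81.92e-6),
                            offset_window = c(157.3e-3, 838.9e-3),
                            bins_per_stage = 16L, max_lag = 1.1,
                            p_primary = 1e-4, p_secondary = 0.02,
                            negative_pair = "negative",
                            n_prebleach = 10L, seed = 1L) {
  if (!file.exists(manifest)) stop("manifest not found: ", manifest)
  if (is.character(calibration)) calibration <- read_calibration_json(calibration)
  if (is.null(calibration)) calibration <- calibration_set()
  stopifnot(inherits(calibration, "calibration_set"))
  if (p_primary <= 0 || p_secondary <= 0) stop("thresholds must be positive")
  structure(list(manifest = manifest, output_dir = output_dir,
                 calibration = calibration, thresholds = thresholds,
                 amp_window = amp_window, offset_window = offset_window,
                 bins_per_stage = as.integer(bins_per_stage),
                 max_lag = max_lag,
                 p_primary = p_primary, p_secondary = p_secondary,
                 negative_pair = negative_pair,
                 n_prebleach = as.integer(n_prebleach),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read and validate a measurement manifest
#'
#' One row per measurement: `id` (unique), `type` (`fccs`, `fcs` or
#' `frap`), `path` (data file, relative paths resolved against the
#' manifest's directory), `pair` (protein pair label, or protein name for
#' fcs/frap), `cell_line`, `location` (`cytosol`, `near` or `far`) and
#' `treatment`.
#'
#' @param path manifest CSV path.
#' @return validated data.frame with absolute `path` column.
#' @export
read_manifest <- function(path) {
  required <- c("id", "type", "path", "pair", "cell_line", "location",
                "treatment")
  if (!file.exists(path)) stop("manifest not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("manifest is missing column(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(df$id))
    stop("duplicate manifest id: ", df$id[duplicated(df$id)][1])
  bad_type <- setdiff(unique(df$type), c("fccs", "fcs", "frap"))
  if (length(bad_type))
    stop("unknown measurement type(s): ", paste(bad_type, collapse = ", "))
  bad_loc <- setdiff(unique(df$location), c("cytosol", "near", "far"))
  if (length(bad_loc))
    stop("unknown location label(s): ", paste(bad_loc, collapse = ", "))
  rel <- !grepl("^(/|[A-Za-z]:)", df$path)
  df$path[rel] <- file.path(dirname(normalizePath(path)), df$path[rel])
  df
}

#' Run the full analysis pipeline
#'
#' Deterministic orchestration: correlate and summarize every FCCS
#' measurement, apply QC, derive Ka and association scores, test every
#' pair's score cohort against the negative control, assemble the
#' association network with its maximal cliques and mutual-exclusivity
#' records, run near-vs-far comparisons where both locations were measured,
#' fit FCS and FRAP records into a dynamics profile with co-dynamics
#' distances, and write all artifacts into the output directory:
#' `results.csv` (tidy, one row per measurement), `network.tsv`,
#' `network.graphml`, `report.json`, `exclusions.log`.
#'
#' Unreadable or malformed input files do not abort the run; they are
#' recorded in the exclusion log and skipped.
#'
#' @param config a [pipeline_config].
#' @return invisible list with `results` (data.frame), `pair_tests`,
#'   `network`, `cliques`, `exclusivity`, `near_far`, `profile`,
#'   `co_dynamics`, `exclusions` (character vector).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  man <- read_manifest(config$manifest)
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  exclusions <- character(0)
  note <- function(id, why)
    exclusions <<- c(exclusions, paste0(id, ": ", why))

  rows <- list(); frap_rows <- list()
  for (i in seq_len(nrow(man))) {
    r <- man[i, ]
    res <- tryCatch({
      if (r$type %in% c("fccs", "fcs")) {
        tr <- read_trace_csv(r$path, dark_rate = config$calibration$dark_rate)
        if (r$type == "fccs") {
          m <- analyze_fccs_measurement(
            list(tr), calib = config$calibration,
            thresholds = config$thresholds,
            amp_window = config$amp_window,
            offset_window = config$offset_window,
            bins_per_stage = config$bins_per_stage, max_lag = config$max_lag,
            metadata = as.list(r))
          if (!m$qc$pass)
            note(r$id, paste("QC:", paste(m$qc$flags, collapse = ",")))
          data.frame(id = r$id, type = r$type, pair = r$pair,
                     cell_line = r$cell_line, location = r$location,
                     treatment = r$treatment,
                     n_gg = m$n_gg, n_rr = m$n_rr, n_rg = m$n_rg,
                     ka_fl = m$ka_fl, score = m$score,
                     c_g = m$c_g, c_r = m$c_r,
                     qc_pass = m$qc$pass,
                     qc_flags = paste(m$qc$flags, collapse = ";"),
                     half_time = NA_real_, mobile_fraction = NA_real_,
                     tau_d = NA_real_, r_squared = NA_real_,
                     stringsAsFactors = FALSE)
        } else {
          cv <- multitau_correlate(tr$green, tr$green,
                                   config$bins_per_stage, config$max_lag)
          f <- fit_fcs(cv, fix_s = config$calibration$s)
          if (!f$converged) note(r$id, "FCS fit did not converge")
          data.frame(id = r$id, type = r$type, pair = r$pair,
                     cell_line = r$cell_line, location = r$location,
                     treatment = r$treatment,
                     n_gg = f$n, n_rr = NA_real_, n_rg = NA_real_,
                     ka_fl = NA_real_, score = NA_real_,
                     c_g = tr$green$count_rate, c_r = NA_real_,
                     qc_pass = f$converged, qc_flags = "",
                     half_time = NA_real_, mobile_fraction = NA_real_,
                     tau_d = f$tau_d, r_squared = f$r_squared,
                     stringsAsFactors = FALSE)
        }
      } else {  # frap
        df <- read_checked_csv(r$path, c("time_s", "intensity", "background"))
        nb <- normalize_frap(df$intensity, df$background, df$time_s,
                             n_prebleach = config$n_prebleach)
        f <- fit_frap(nb)
        if (!f$valid)
          note(r$id, sprintf("FRAP fit excluded (R^2 = %.3f <= 0.7 or no fit)",
                             f$r_squared %||% NA))
        data.frame(id = r$id, type = r$type, pair = r$pair,
                   cell_line = r$cell_line, location = r$location,
                   treatment = r$treatment,
                   n_gg = NA_real_, n_rr = NA_real_, n_rg = NA_real_,
                   ka_fl = NA_real_, score = NA_real_,
                   c_g = NA_real_, c_r = NA_real_,
                   qc_pass = f$valid, qc_flags = "",
                   half_time = f$half_time,
                   mobile_fraction = f$mobile_fraction,
                   tau_d = NA_real_, r_squared = f$r_squared,
                   stringsAsFactors = FALSE)
      }
    }, error = function(e) {
      note(r$id, paste("read/analysis error:", conditionMessage(e)))
      NULL
    })
    if (!is.null(res)) rows[[length(rows) + 1L]] <- res
  }
  results <- if (length(rows)) do.call(rbind, rows) else data.frame()

  # --- cohort statistics -------------------------------------------------
  pair_tests <- data.frame()
  network <- NULL; cliques <- list(); exclusivity <- list()
  if (nrow(results)) {
    fccs <- results[results$type == "fccs" & results$qc_pass &
                      !is.na(results$score), , drop = FALSE]
    neg <- fccs$score[fccs$pair == config$negative_pair]
    test_pairs <- setdiff(unique(fccs$pair), config$negative_pair)
    if (length(neg) && length(test_pairs)) {
      pt <- lapply(sort_c(test_pairs), function(p) {
        sc <- fccs$score[fccs$pair == p]
        if (!length(sc)) {
          note(p, "empty surviving cohort for declared pair")
          return(NULL)
        }
        mt <- median_association_test(sc, neg, "greater")
        ab <- strsplit(p, "--", fixed = TRUE)[[1]]
        if (length(ab) != 2) ab <- c(p, "unknown")
        data.frame(pair = p, protein_a = ab[1], protein_b = ab[2],
                   n_cells = length(sc), p_primary = mt$p_value,
                   ka_median = stats::median(fccs$ka_fl[fccs$pair == p],
                                             na.rm = TRUE),
                   ka_mad = raw_mad(fccs$ka_fl[fccs$pair == p][
                     is.finite(fccs$ka_fl[fccs$pair == p])]),
                   score_median = stats::median(sc),
                   stringsAsFactors = FALSE)
      })
      pair_tests <- do.call(rbind, Filter(Negate(is.null), pt))
      if (!is.null(pair_tests) && nrow(pair_tests)) {
        network <- build_network(pair_tests, config$p_primary,
                                 config$p_secondary)
        cliques <- find_ternary_complexes(network)
        exclusivity <- infer_mutual_exclusivity(network)
      }
    }
    pair_tests <- pair_tests %||% data.frame()
  }

  # --- near/far comparisons ---------------------------------------------
  near_far <- list()
  if (nrow(results)) {
    fccs_all <- results[results$type == "fccs" & results$qc_pass &
                          !is.na(results$score), , drop = FALSE]
    for (p in sort_c(unique(fccs_all$pair))) {
      s_near <- fccs_all[fccs_all$pair == p & fccs_all$location == "near", ]
      s_far <- fccs_all[fccs_all$pair == p & fccs_all$location == "far", ]
      if (!nrow(s_near) || !nrow(s_far)) next
      entry <- list(pair = p,
                    uncoupled = near_far_uncoupled_test(s_near$score,
                                                        s_far$score))
      if (nrow(s_near) == nrow(s_far)) {
        s_near <- s_near[order(s_near$id), ]; s_far <- s_far[order(s_far$id), ]
        entry$coupled <- near_far_coupled_test(s_near$score, s_far$score)
      }
      near_far[[p]] <- entry
    }
  }

  # --- dynamics ----------------------------------------------------------
  profile <- data.frame(); co_dyn <- NULL
  if (nrow(results)) {
    dyn <- results[results$type %in% c("frap", "fcs"), , drop = FALSE]
    if (nrow(dyn)) {
      dyn_df <- data.frame(protein = dyn$pair, half_time = dyn$half_time,
                           mobile_fraction = dyn$mobile_fraction,
                           tau_d = dyn$tau_d, valid = dyn$qc_pass,
                           stringsAsFactors = FALSE)
      profile <- withCallingHandlers(
        dynamics_profile(dyn_df),
        warning = function(w) {
          note("dynamics", conditionMessage(w))
          invokeRestart("muffleWarning")
        })
      if (nrow(profile) >= 3 &&
          all(c("median_half_time", "median_mobile_fraction") %in%
              names(profile)) &&
          !anyNA(profile$median_half_time) &&
          !anyNA(profile$median_mobile_fraction))
        co_dyn <- tryCatch(co_dynamics_distance(profile),
                           error = function(e) NULL)
    }
  }

  # --- artifacts ---------------------------------------------------------
  header <- sprintf("# fccsnet %s | seed %d | config hash %s",
                    as.character(utils::packageVersion("fccsnet")),
                    config$seed, config_hash(config))
  res_path <- file.path(config$output_dir, "results.csv")
  writeLines(header, res_path)
  suppressWarnings(write.table(results, res_path, sep = ",", row.names = FALSE,
                               append = TRUE, quote = TRUE))
  if (!is.null(network))
    write_network(network, file.path(config$output_dir, "network.tsv"),
                  file.path(config$output_dir, "network.graphml"))
  report <- list(
    package_version = as.character(utils::packageVersion("fccsnet")),
    seed = config$seed, config_hash = config_hash(config),
    n_measurements = nrow(results),
    n_excluded = length(exclusions),
    pair_tests = pair_tests,
    cliques = lapply(cliques, identity),
    mutual_exclusivity = exclusivity,
    near_far = near_far,
    dynamics_profile = profile)
  jsonlite::write_json(report, file.path(config$output_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  writeLines(c(header, exclusions),
             file.path(config$output_dir, "exclusions.log"))

  invisible(list(results = results, pair_tests = pair_tests,
                 network = network, cliques = cliques,
                 exclusivity = exclusivity, near_far = near_far,
                 profile = profile, co_dynamics = co_dyn,
                 exclusions = exclusions))
}

# stable short hash of the analysis-relevant configuration (for output
# provenance headers); file-system locations are excluded so identical
# analyses hash identically regardless of where they read/write
config_hash <- function(config) {
  x <- unclass(config)
  x$calibration$provenance <- NULL
  x$manifest <- NULL
  x$output_dir <- NULL
  substr(digest_string(paste(deparse(x), collapse = "")), 1, 12)
}

# dependency-free polynomial string hash (exact in double arithmetic)
digest_string <- function(s) {
  bytes <- utf8ToInt(s)
  h1 <- 0; h2 <- 0
  for (b in bytes) {
    h1 <- (h1 * 31 + b) %% 1000000007
    h2 <- (h2 * 37 + b) %% 998244353
  }
  sprintf("%08x%08x", h1, h2)
}
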