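stop_rows <- function(file, rows, msg) {
  stop(file, ": ", msg, " at data row(s) ",
       paste(head(rows, 10), collapse = ", "),
       if (length(rows) > 10) " ..." else "")
}

#' Read individual respirometry measurements from CSV
#'
#' Expected columns: `species`, `stream`, `mass_mg`, `T_acute_C`,
#' `T_chronic_C`, `rate_J_per_h` (UTF-8, header row). Temperatures are
#' converted to kelvin on ingestion and validated against a plausible
#' 270--310 K range.
#'
#' @param path CSV file.
#' @return data frame with kelvin columns `T_acute_K`, `T_chronic_K`
#'   appended.
#' @export
read_measurements <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "stream", "mass_mg", "T_acute_C", "T_chronic_C",
            "rate_J_per_h")
  missing <- setdiff(need, names(d))
  if (length(missing)) stop(path, " lacks columns: ", paste(missing, collapse = ", "))
  bad <- which(!is.finite(d$mass_mg) | d$mass_mg <= 0)
  if (length(bad)) stop_rows(path, bad, "non-positive body mass")
  bad <- which(!is.finite(d$rate_J_per_h) | d$rate_J_per_h <= 0)
  if (length(bad)) stop_rows(path, bad, "non-positive metabolic rate")
  d$T_acute_K <- celsius_to_kelvin(d$T_acute_C)
  d$T_chronic_K <- celsius_to_kelvin(d$T_chronic_C)
  for (col in c("T_acute_K", "T_chronic_K")) {
    bad <- which(d[[col]] < 270 | d[[col]] > 310)
    if (length(bad)) stop_rows(path, bad, paste("implausible temperature in", col))
  }
  d
}

#' Write measurements to CSV
#'
#' @param data measurement data frame.
#' @param path output file.
#' @export
write_measurements <- function(data, path) {
  cols <- c("species", "stream", "mass_mg", "T_acute_C", "T_chronic_C",
            "rate_J_per_h")
  write.csv(data[, intersect(cols, names(data))], path, row.names = FALSE)
  invisible(path)
}

#' Read a food web from node and edge CSV files
#'
#' The node file needs columns `label`, `resource_type`, `biomass_mg_m2`,
#' `body_mass_mg`; the edge file needs `resource`, `consumer` referring to
#' node labels. Validation errors name the offending data rows.
#'
#' @param node_path,edge_path CSV files.
#' @return a [food_web()].
#' @export
read_food_web <- function(node_path, edge_path) {
  nodes <- read.csv(node_path, stringsAsFactors = FALSE)
  edges <- read.csv(edge_path, stringsAsFactors = FALSE)
  need <- c("label", "resource_type", "biomass_mg_m2", "body_mass_mg")
  missing <- setdiff(need, names(nodes))
  if (length(missing)) stop(node_path, " lacks columns: ", paste(missing, collapse = ", "))
  missing <- setdiff(c("resource", "consumer"), names(edges))
  if (length(missing)) stop(edge_path, " lacks columns: ", paste(missing, collapse = ", "))
  bad <- which(!is.finite(nodes$biomass_mg_m2) | nodes$biomass_mg_m2 <= 0)
  if (length(bad)) stop_rows(node_path, bad, "non-positive biomass")
  unknown <- which(!edges$resource %in% nodes$label | !edges$consumer %in% nodes$label)
  if (length(unknown)) stop_rows(edge_path, unknown, "edge refers to unknown node label")
  n <- nrow(nodes)
  A <- matrix(0, n, n, dimnames = list(nodes$label, nodes$label))
  A[cbind(edges$resource, edges$consumer)] <- 1
  food_web(nodes, A)
}

#' Write a food web to node and edge CSV files
#'
#' @param web a [food_web()].
#' @param node_path,edge_path output files.
#' @export
write_food_web <- function(web, node_path, edge_path) {
  stopifnot(inherits(web, "food_web"))
  write.csv(web$nodes[, c("label", "resource_type", "biomass_mg_m2",
                          "body_mass_mg")], node_path, row.names = FALSE)
  idx <- which(web$adjacency == 1, arr.ind = TRUE)
  edges <- data.frame(resource = rownames(web$adjacency)[idx[, 1]],
                      consumer = colnames(web$adjacency)[idx[, 2]])
  write.csv(edges, edge_path, row.names = FALSE)
  invisible(node_path)
}

#' Read oxygen traces and compute per-chamber rates
#'
#' Long-format CSV with columns `batch_id`, `chamber_id`, `is_control`,
#' `t_s`, `o2_umol_per_L`, `volume_L`. Each batch must contain exactly one
#' control chamber; every animal chamber is corrected against its batch's
#' control via [trace_to_rate()].
#'
#' @param path CSV file.
#' @return data frame with one row per animal chamber: `batch_id`,
#'   `chamber_id`, `rate_umol_h`, `rate_J_per_h`, `low_oxygen`.
#' @export
process_traces <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("batch_id", "chamber_id", "is_control", "t_s", "o2_umol_per_L",
            "volume_L")
  missing <- setdiff(need, names(d))
  if (length(missing)) stop(path, " lacks columns: ", paste(missing, collapse = ", "))
  out <- list()
  for (b in unique(d$batch_id)) {
    db <- d[d$batch_id == b, ]
    ctrl_ids <- unique(db$chamber_id[db$is_control %in% c(TRUE, 1, "TRUE")])
    if (length(ctrl_ids) != 1) {
      stop(path, ": batch ", b, " has ", length(ctrl_ids),
           " control chambers (exactly 1 required)")
    }
    dc <- db[db$chamber_id == ctrl_ids, ]
    control <- oxygen_trace(dc$t_s, dc$o2_umol_per_L, dc$volume_L[1],
                            is_control = TRUE)
    for (ch in setdiff(unique(db$chamber_id), ctrl_ids)) {
      da <- db[db$chamber_id == ch, ]
      animal <- oxygen_trace(da$t_s, da$o2_umol_per_L, da$volume_L[1])
      rate <- trace_to_rate(animal, control)
      out[[length(out) + 1]] <- data.frame(
        batch_id = b, chamber_id = ch,
        rate_umol_h = as.numeric(rate),
        rate_J_per_h = o2_rate_to_joules(max(0, as.numeric(rate))),
        low_oxygen = attr(rate, "low_oxygen"))
    }
  }
  do.call(rbind, out)
}

#' Write a flux solution to link/node CSVs and a JSON summary
#'
#' @param sol a [solve_fluxes()] solution.
#' @param link_path,node_path,summary_path output files (any may be `NULL`
#'   to skip).
#' @return the summary list (`F`, `F_H`, `F_D`, `F_P`) invisibly.
#' @export
write_flux_solution <- function(sol, link_path = NULL, node_path = NULL,
                                summary_path = NULL) {
  stopifnot(inherits(sol, "flux_solution"))
  idx <- which(sol$F > 0, arr.ind = TRUE)
  links <- data.frame(
    resource = rownames(sol$F)[idx[, 1]], consumer = colnames(sol$F)[idx[, 2]],
    w = sol$params$w[idx], e = sol$params$e[idx], F = sol$F[idx],
    ewF = sol$ewF[idx])
  nodes <- data.frame(label = names(sol$x), Z = sol$params$Z,
                      gain = sol$gain, loss = sol$loss,
                      residual = sol$residual)
  dec <- trophic_decomposition(sol)
  summary <- list(F = total_flux(sol), F_H = dec[["F_H"]], F_D = dec[["F_D"]],
                  F_P = dec[["F_P"]])
  if (!is.null(link_path)) write.csv(links, link_path, row.names = FALSE)
  if (!is.null(node_path)) write.csv(nodes, node_path, row.names = FALSE)
  if (!is.null(summary_path)) {
    jsonlite::write_json(summary, summary_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(summary)
}

#' Run the analysis pipeline end to end
#'
#' Orchestrates the stages on synthetic or user-supplied inputs in
#' dependency order: `simulate` (respirometry dataset + web ensemble),
#' `qc` (population regressions and filtering), `fit` (random- and
#' fixed-structure selection, coefficient export), `warm` (per-web warming
#' comparison, Wilcoxon tests, amplification), and `spatial` (when a site
#' table with coordinates is supplied). Every artefact is written under
#' `out_dir` and listed in a manifest with its md5 checksum, the seed and
#' record counts, so deterministic stages can be audited by rerunning.
#'
#' @param out_dir output directory (created if needed).
#' @param seed integer seed controlling all randomness.
#' @param stages character subset of
#'   `c("simulate", "qc", "fit", "warm", "spatial")`.
#' @param sim_config a [metabolic_sim_config()] (its seed is overridden by
#'   `seed`).
#' @param n_webs number of synthetic webs for the warming stage.
#' @param dT_C warming increment (degrees C).
#' @param T_acute_K,T_chronic_K baseline temperatures for the flux stage.
#' @param sites optional data frame (`site`, `lat`, `lon`, `mean_temp_C`)
#'   enabling the spatial stage.
#' @param verbose print stage progress.
#' @return the manifest data frame (stage, artefact, md5, n_records),
#'   invisibly; the full results are attached as attribute `results`.
#' @export
run_pipeline <- function(out_dir, seed = 1L,
                         stages = c("simulate", "qc", "fit", "warm"),
                         sim_config = metabolic_sim_config(),
                         n_webs = 14, dT_C = 2,
                         T_acute_K = celsius_to_kelvin(12),
                         T_chronic_K = celsius_to_kelvin(12),
                         sites = NULL, verbose = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory ", out_dir)
  known <- c("simulate", "qc", "fit", "warm", "spatial")
  if (!all(stages %in% known)) {
    stop("unknown stage(s): ", paste(setdiff(stages, known), collapse = ", "))
  }
  say <- function(...) if (verbose) message(...)
  manifest <- data.frame(stage = character(), artefact = character(),
                         md5 = character(), n_records = integer())
  add <- function(stage, path, n) {
    manifest <<- rbind(manifest, data.frame(
      stage = stage, artefact = basename(path),
      md5 = unname(tools::md5sum(path)), n_records = n))
  }
  results <- list(seed = seed)

  sim_config$seed <- as.integer(seed)
  data <- NULL
  if ("simulate" %in% stages) {
    say("simulate: respirometry dataset")
    data <- simulate_metabolic_dataset(sim_config)
    f <- file.path(out_dir, "measurements.csv")
    write_measurements(data, f); add("simulate", f, nrow(data))
    truth <- attr(data, "truth")
    ft <- file.path(out_dir, "truth.json")
    jsonlite::write_json(list(
      seed = seed,
      coefficients = unclass(truth$coefficients),
      re_sds = truth$config$re_sds, residual_sd = truth$config$residual_sd),
      ft, auto_unbox = TRUE, digits = NA)
    add("simulate", ft, 1L)
    results$data <- data
  }
  if ("qc" %in% stages) {
    if (is.null(data)) stop("qc stage needs the simulate stage (or supply data)")
    say("qc: population regressions and filtering")
    fits <- population_regressions(data)
    qc <- qc_filter(fits, data)
    f <- file.path(out_dir, "qc_report.csv")
    write_qc_report(qc$report, f); add("qc", f, nrow(qc$report))
    data <- qc$kept
    results$qc <- qc
  }
  if ("fit" %in% stages) {
    if (is.null(data)) stop("fit stage needs data from simulate/qc")
    say("fit: model selection")
    prepared <- prepare_lmm_data(data)
    rnd <- select_random_structure(prepared)
    sel <- select_fixed_structure(prepared, rnd$random_terms)
    f <- file.path(out_dir, "model_comparison.csv")
    write_comparison_table(sel$table, f); add("fit", f, nrow(sel$table))
    co <- tryCatch(as_metabolic_coefficients(sel$fit), error = function(e) NULL)
    if (!is.null(co)) {
      f <- file.path(out_dir, "coefficients_fitted.json")
      write_coefficients(co, f); add("fit", f, 1L)
    }
    results$fit <- sel
    results$random <- rnd
  }
  if ("warm" %in% stages) {
    say("warm: ", n_webs, "-web warming comparison")
    webs <- lapply(seq_len(n_webs), function(i) {
      simulate_web(web_sim_config(seed = seed * 1000L + i))
    })
    comparisons <- lapply(webs, warming_scenario,
                          coeffs_plastic = default_coefficients("plasticity"),
                          coeffs_fixed = default_coefficients("no_plasticity"),
                          T_acute_K = T_acute_K, T_chronic_K = T_chronic_K,
                          dT_C = dT_C)
    cw <- compare_warming(comparisons)
    report <- list(
      seed = seed, dT_C = dT_C, n_webs = n_webs,
      amplification_mean_pct = cw$amplification$mean,
      amplification_se_pct = cw$amplification$se,
      tests = lapply(cw$tests, function(t) list(V = t$V, n = t$n, p = t$p)))
    f <- file.path(out_dir, "warming_report.json")
    jsonlite::write_json(report, f, auto_unbox = TRUE, digits = NA)
    add("warm", f, n_webs)
    results$warming <- cw
  }
  if ("spatial" %in% stages) {
    if (is.null(sites)) stop("spatial stage needs a site table")
    say("spatial: autocorrelation diagnostics")
    D <- great_circle_matrix(sites)
    Dt <- as.matrix(dist(sites$mean_temp_C))
    mt <- mantel_test(D, Dt, seed = seed)
    vals <- sites$mean_temp_C
    mi <- morans_i_test(vals, inverse_distance_weights(D), seed = seed)
    f <- file.path(out_dir, "spatial.json")
    jsonlite::write_json(list(mantel_r = mt$r, mantel_p = mt$p,
                              moran_i = mi$I, moran_p = mi$p),
                         f, auto_unbox = TRUE, digits = NA)
    add("spatial", f, nrow(sites))
    results$spatial <- list(mantel = mt, moran = mi)
  }
  mf <- file.path(out_dir, "manifest.csv")
  write.csv(manifest, mf, row.names = FALSE)
  invisible(structure(manifest, results = results))
}
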