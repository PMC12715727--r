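.all_stages <- c("exclude", "code", "describe", "correlate", "regress",
                 "oe", "network", "stability", "communities")

# deterministic per-stage seed derived from the master seed and stage name;
# kept strictly below 2^31
stage_seed <- function(master, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(master) * 10007 + h * 131) %% 2147480000L)
}

#' Pipeline configuration
#'
#' Bundles the input source, stage switches, statistical settings, and the
#' master seed for [run_pipeline()]. Every stochastic stage derives its
#' effective seed deterministically from `seed` and the stage name, so
#' stages can be re-run in isolation reproducibly. Unknown setting names
#' are rejected.
#'
#' @param input Path to a survey CSV, or NULL to use `synthetic`.
#' @param synthetic A [synthetic_config()] (used when `input` is NULL).
#' @param mapping Optional column-name mapping for foreign headers.
#' @param stages Which stages to report (subset of exclude, code, describe,
#'   correlate, regress, oe, network, stability, communities).
#' @param seed Master seed.
#' @param output_dir Optional directory for per-stage artifacts.
#' @param ... Statistical settings overriding the defaults: `ci_method`,
#'   `B` (O/E bootstrap), `gamma`, `rule`, `resolution`, `weight_transform`,
#'   `drop_fractions`, `B_per_fraction`, `B_edge_ci`, `top_k`,
#'   `mode_impute`.
#' @return Object of class `hrb_config`.
#' @export
pipeline_config <- function(input = NULL, synthetic = NULL, mapping = NULL,
                            stages = .all_stages, seed = 1L,
                            output_dir = NULL, ...) {
  settings <- list(ci_method = "bootstrap", B = 1000, gamma = 0.25,
                   rule = "AND", resolution = 1, weight_transform = "abs",
                   drop_fractions = seq(0.1, 0.7, by = 0.1),
                   B_per_fraction = 100, B_edge_ci = 1000, top_k = 10,
                   mode_impute = FALSE)
  extra <- list(...)
  unknown <- setdiff(names(extra), names(settings))
  if (length(unknown))
    stop("unknown settings: ", paste(unknown, collapse = ", "))
  settings[names(extra)] <- extra
  bad <- setdiff(stages, .all_stages)
  if (length(bad)) stop("unknown stages: ", paste(bad, collapse = ", "))
  if (is.null(input) && is.null(synthetic))
    synthetic <- synthetic_config(n_records = 1000, seed = seed)
  structure(list(input = input, synthetic = synthetic, mapping = mapping,
                 stages = stages, seed = as.integer(seed),
                 output_dir = output_dir, settings = settings),
            class = "hrb_config")
}

#' Run the full co-occurrence and clustering analysis
#'
#' Executes the stages in order — exclusions, behavior coding, descriptives,
#' behavior-count/outcome correlation, co-occurrence logistic regression,
#' O/E clustering (overall and by gender), Ising network estimation,
#' stability assessment, and Louvain community detection — and returns a
#' consolidated, fully seeded report. Stages absent from `config$stages`
#' are omitted from the report. If `config$output_dir` is set, per-stage
#' CSV/JSON/GraphML artifacts and the consolidated JSON report are written
#' there.
#'
#' @param config An [pipeline_config()] object.
#' @return List of class `hrb_report`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "hrb_config"))
  st <- config$settings
  stages <- config$stages
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  raw <- if (!is.null(config$input)) {
    run_stage("input", read_survey(config$input, config$mapping))
  } else {
    run_stage("input", generate_survey_table(config$synthetic))
  }

  excl <- run_stage("exclude", apply_exclusions(raw))
  tab <- excl$table
  if (nrow(tab) == 0) stop("no records left after exclusions")
  X <- run_stage("code", code_behaviors(tab))
  bc <- behavior_count(X)

  report <- list(
    package_version = as.character(utils::packageVersion("hrbnet")),
    settings = c(st, list(seed = config$seed, stages = stages,
                          n_input = nrow(raw), n_analyzed = nrow(tab)))
  )
  if ("exclude" %in% stages) report$exclusions <- excl$log
  if ("code" %in% stages)
    report$coding <- list(n_records = nrow(X), behaviors = colnames(X),
                          column_sums = colSums(X))
  if ("describe" %in% stages) {
    report$prevalence <- run_stage("describe", prevalence(X))
    report$count_distribution <- bc$distribution
    report$prop_multiple <- bc$prop_multiple
  }
  if ("correlate" %in% stages) {
    report$correlation <- run_stage("correlate", {
      sc <- score_outcomes(tab)
      idx <- if (is.null(tab$id)) sc$id else match(sc$id, tab$id)
      list(qol = spearman_correlation(bc$counts[idx], sc$qol_score),
           health = spearman_correlation(bc$counts[idx], sc$health_score),
           n_dropped_missing_ratings = attr(sc, "n_dropped"))
    })
  }
  if ("regress" %in% stages) {
    fit <- run_stage("regress",
      fit_cooccurrence_logistic(tab, as.integer(bc$counts >= 2),
                                mode_impute = st$mode_impute))
    report$logistic <- list(terms = fit$terms,
                            intercept_odds = unname(fit$intercept_odds),
                            n_used = fit$n_used, n_dropped = fit$n_dropped,
                            converged = fit$converged)
  }
  if ("oe" %in% stages) {
    report$oe <- run_stage("oe", list(
      overall = oe_table(X, method = st$ci_method, B = st$B,
                         seed = stage_seed(config$seed, "oe")),
      by_gender = if (!is.null(tab$gender))
        stratified_oe(X, tab$gender, method = st$ci_method, B = st$B,
                      seed = stage_seed(config$seed, "oe_strata"),
                      top_k = st$top_k)
    ))
  }
  need_net <- any(c("network", "stability", "communities") %in% stages)
  if (need_net) {
    fit <- run_stage("network", elasso_fit(X, gamma = st$gamma,
                                           rule = st$rule))
    if ("network" %in% stages)
      report$network <- list(W = fit$W, tau = fit$tau,
                             metrics = network_metrics(fit$W),
                             gamma = st$gamma, rule = st$rule)
    if ("stability" %in% stages) {
      report$stability <- run_stage("stability", {
        ci <- bootstrap_edge_ci(X, B = st$B_edge_ci,
                                seed = stage_seed(config$seed, "edge_ci"),
                                gamma = st$gamma, rule = st$rule)
        cds <- case_dropping_stability(
          X, drop_fractions = st$drop_fractions,
          B_per_fraction = st$B_per_fraction,
          seed = stage_seed(config$seed, "case_dropping"),
          gamma = st$gamma, rule = st$rule)
        list(edge_ci = ci, summary = cds$summary,
             cs_coefficient = cds$cs_coefficient)
      })
    }
    if ("communities" %in% stages) {
      report$communities <- run_stage("communities", {
        part <- louvain(fit$W, weight_transform = st$weight_transform,
                        resolution = st$resolution,
                        seed = stage_seed(config$seed, "louvain"))
        list(membership = part$membership,
             modularity_q = part$modularity_q,
             n_communities = part$n_communities)
      })
    }
  }
  class(report) <- "hrb_report"
  if (!is.null(config$output_dir)) write_report(report, config$output_dir)
  report
}

#' Write a pipeline report and its per-stage artifacts
#'
#' Writes `report.json` (12 significant digits, so identical runs produce
#' identical bytes) plus CSV tables for prevalence, the logistic model, and
#' O/E rankings, a GraphML network, and a weighted edge list, for whichever
#' stages the report contains.
#'
#' @param report An `hrb_report`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the report path.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(dir, "report.json")
  jsonlite::write_json(unclass(report), path, digits = 12,
                       auto_unbox = TRUE, na = "null", pretty = TRUE)
  if (!is.null(report$prevalence))
    write.csv(report$prevalence, file.path(dir, "prevalence.csv"),
              row.names = FALSE)
  if (!is.null(report$logistic))
    write.csv(report$logistic$terms, file.path(dir, "logistic.csv"),
              row.names = FALSE)
  if (!is.null(report$oe)) {
    write.csv(report$oe$overall, file.path(dir, "oe_overall.csv"),
              row.names = FALSE)
    for (s in names(report$oe$by_gender))
      write.csv(report$oe$by_gender[[s]],
                file.path(dir, paste0("oe_", s, ".csv")), row.names = FALSE)
  }
  if (!is.null(report$network)) {
    mem <- if (!is.null(report$communities)) report$communities$membership
    write_graphml(report$network$W, file.path(dir, "network.graphml"), mem)
    write_edge_list(report$network$W, file.path(dir, "edges.csv"))
  }
  if (!is.null(report$stability))
    write.csv(report$stability$edge_ci, file.path(dir, "edge_ci.csv"),
              row.names = FALSE)
  invisible(path)
}

#' @export
print.hrb_report <- function(x, ...) {
  cat("hrbnet analysis report (n analyzed =", x$settings$n_analyzed, ")\n")
  cat("stages:", paste(x$settings$stages, collapse = ", "), "\n")
  if (!is.null(x$prop_multiple))
    cat("proportion with >= 2 behaviors:",
        format(x$prop_multiple, digits = 4), "\n")
  if (!is.null(x$network))
    cat("network density:", format(x$network$metrics$density, digits = 4),
        "| mean strength:",
        format(x$network$metrics$mean_strength, digits = 4), "\n")
  if (!is.null(x$communities))
    cat("communities:", x$communities$n_communities, "(Q =",
        format(x$communities$modularity_q, digits = 4), ")\n")
  invisible(x)
}
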