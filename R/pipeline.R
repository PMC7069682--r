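#' Build a validated run configuration
#'
#' @param n_iter null-model iterations (>= 99; default 999).
#' @param seed master seed; per-stage substreams are derived from it so
#'   stages rerun in isolation reproduce the pipeline stream.
#' @param pic_stat statistic for the continuous signal test
#'   (`"variance"` or `"mean_abs"`).
#' @param gower_weights optional named per-trait Gower weights.
#' @param whc soil water holding capacity for the water balance (mm).
#' @param p_lower,p_upper pattern-classification thresholds.
#' @param collinearity_threshold Pearson |r| cutoff before the PCA.
#' @param map_rule species-label mapping rule for validation (see
#'   [validate_dataset()]).
#' @param drop_unmatched drop community species missing from tree/traits
#'   instead of aborting.
#' @return list of class `run_config`.
#' @export
run_config <- function(n_iter = 999, seed = NULL, pic_stat = "variance",
                       gower_weights = NULL, whc = 100,
                       p_lower = 0.025, p_upper = 0.975,
                       collinearity_threshold = 0.7,
                       map_rule = "strip_site_suffix",
                       drop_unmatched = FALSE) {
  stopifnot(n_iter >= 99,
            p_lower > 0, p_lower < 0.5, p_upper > 0.5, p_upper < 1,
            collinearity_threshold > 0)
  structure(list(n_iter = n_iter, seed = seed, pic_stat = pic_stat,
                 gower_weights = gower_weights, whc = whc,
                 p_lower = p_lower, p_upper = p_upper,
                 collinearity_threshold = collinearity_threshold,
                 map_rule = map_rule, drop_unmatched = drop_unmatched),
            class = "run_config")
}

#' Run the full assembly-inference pipeline
#'
#' Stages, in order: label validation; functional trees; phylogenetic
#' signal per trait; SES of MPD/PW/PW-alpha/PW-beta per site;
#' phylobetadiversity with distance decay; per-site water-balance ledgers;
#' collinearity filter + PCA with broken-stick retention; regression of
#' SES on the significant axes. All tables are written as CSV into
#' `outdir` together with a machine-readable manifest and a plain-text
#' report. Any stage failure aborts with the stage name.
#'
#' @param tree regional phylogeny (`phylo`), or a path to a newick file.
#' @param traits a `trait_table`, or `c(values, schema)` paths.
#' @param comm a `community_matrix`, or a path.
#' @param climate named list of `climate_series` (or a climate CSV path);
#'   optional — stage skipped when `NULL`.
#' @param env site x variable data.frame (or CSV path with a `site`
#'   column); optional — ordination/regression skipped when `NULL`.
#' @param outdir output directory.
#' @param config a [run_config()].
#' @return list of class `pipeline_result` with every stage's table,
#'   invisibly; side effect: files under `outdir`.
#' @export
run_pipeline <- function(tree, traits, comm, climate = NULL, env = NULL,
                         outdir, config = run_config()) {
  stage <- function(name, code) {
    tryCatch(code, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  if (is.character(tree)) tree <- read_newick(tree)
  if (is.character(traits)) traits <- read_trait_table(traits[1], traits[2])
  if (is.character(comm)) comm <- read_community_matrix(comm)
  if (is.character(climate)) climate <- read_climate_csv(climate, config$whc)
  if (is.character(env)) {
    env <- read.csv(env, stringsAsFactors = FALSE)
    rownames(env) <- env$site
    env$site <- NULL
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  out <- list(config = config)

  report <- stage("validate", validate_dataset(tree, traits, comm,
                                               map_rule = config$map_rule))
  out$validation <- report
  if (!report$ok) {
    if (!config$drop_unmatched)
      stop("pipeline stage 'validate' failed: unmapped species (",
           length(report$missing_from_tree), " missing from tree, ",
           length(report$missing_from_traits), " missing from traits); ",
           "set drop_unmatched = TRUE to drop them", call. = FALSE)
    drop <- union(report$missing_from_tree, report$missing_from_traits)
    keep <- setdiff(colnames(comm$incidence), drop)
    comm <- community_matrix(comm$incidence[, keep, drop = FALSE],
                             comm$metadata)
  }

  out$signal <- stage("signal",
    signal_table(tree, traits, n_iter = config$n_iter,
                 seed = derive_seed(config$seed, "signal"),
                 stat = config$pic_stat))
  write.csv(out$signal, file.path(outdir, "signal.csv"), row.names = FALSE)

  out$ses <- stage("structure",
    run_structure_analysis(comm, tree, traits, n_iter = config$n_iter,
                           seed = derive_seed(config$seed, "structure"),
                           lower = config$p_lower, upper = config$p_upper,
                           gower_weights = config$gower_weights))
  write.csv(out$ses, file.path(outdir, "ses.csv"), row.names = FALSE)

  has_coords <- !is.null(comm$metadata) &&
    all(c("latitude", "longitude") %in% names(comm$metadata))
  out$phylobeta <- stage("phylobeta",
    phylobeta_analysis(comm, tree, n_iter = config$n_iter,
                       seed = derive_seed(config$seed, "phylobeta"),
                       decay = has_coords))
  write.csv(out$phylobeta$pairs, file.path(outdir, "phylobeta.csv"),
            row.names = FALSE)

  if (!is.null(climate)) {
    out$water_balance <- stage("climate", lapply(climate, water_balance))
    for (wb in out$water_balance)
      write_water_balance(wb, file.path(outdir, paste0(
        "water_balance_", attr(wb, "site"), ".csv")))
  }

  if (!is.null(env)) {
    out$retained_vars <- stage("ordinate",
      collinearity_filter(env, config$collinearity_threshold))
    out$pca <- stage("ordinate",
      pca_broken_stick(env[, out$retained_vars, drop = FALSE]))
    write.csv(data.frame(site = rownames(out$pca$scores), out$pca$scores),
              file.path(outdir, "pca_scores.csv"), row.names = FALSE)
    write.csv(data.frame(variable = rownames(out$pca$correlations),
                         out$pca$correlations),
              file.path(outdir, "pca_loadings.csv"), row.names = FALSE)
    write.csv(data.frame(axis = seq_along(out$pca$proportion),
                         proportion = out$pca$proportion,
                         broken_stick = out$pca$broken_stick,
                         significant = out$pca$significant),
              file.path(outdir, "broken_stick.csv"), row.names = FALSE)
    if (any(out$pca$significant)) {
      out$regression <- stage("regress",
        gradient_regression(out$ses, out$pca))
      write.csv(out$regression$coefficients,
                file.path(outdir, "regression.csv"), row.names = FALSE)
      write.csv(out$regression$scatter,
                file.path(outdir, "ses_gradient_scatter.csv"),
                row.names = FALSE)
    }
  }

  manifest <- list(
    package = "stressdom",
    package_version = as.character(utils::packageVersion("stressdom")),
    r_version = R.version.string,
    seed = config$seed, n_iter = config$n_iter,
    stages = names(out)[!vapply(out, is.null, logical(1))],
    files = list.files(outdir))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  writeLines(pipeline_report(out), file.path(outdir, "report.txt"))
  class(out) <- "pipeline_result"
  invisible(out)
}

pipeline_report <- function(out) {
  lines <- c("stressdom pipeline report", "=========================", "")
  if (!is.null(out$signal)) {
    sig <- sum(out$signal$p < 0.05)
    lines <- c(lines, sprintf(
      "Phylogenetic signal: %d / %d traits with p < 0.05.",
      sig, nrow(out$signal)))
  }
  if (!is.null(out$ses)) {
    for (m in unique(out$ses$metric)) {
      sub <- out$ses[out$ses$metric == m, ]
      lines <- c(lines, sprintf(
        "%s: %d clustered, %d random, %d overdispersed site(s).",
        m, sum(sub$pattern == "clustered"), sum(sub$pattern == "random"),
        sum(sub$pattern == "overdispersed")))
    }
  }
  if (!is.null(out$phylobeta)) {
    lines <- c(lines, sprintf(
      "Phylobetadiversity: %d / %d pairs clustered; Mantel r = %.3f (p = %s).",
      sum(out$phylobeta$pairs$pattern == "clustered"),
      nrow(out$phylobeta$pairs), out$phylobeta$mantel_r,
      format(out$phylobeta$mantel_p)))
  }
  if (!is.null(out$water_balance)) {
    for (wb in out$water_balance) {
      a <- attr(wb, "annual")
      lines <- c(lines, sprintf(
        "Water balance %s (%s): R %.0f, PET %.0f, AET %.0f, DEF %.0f, EXC %.0f mm.",
        attr(wb, "site"), attr(wb, "branch"), a["rainfall"], a["pet"],
        a["aet"], a["def"], a["exc"]))
    }
  }
  if (!is.null(out$pca)) {
    lines <- c(lines, sprintf(
      "PCA: axes beyond broken stick: %s (proportions %s).",
      paste(which(out$pca$significant), collapse = ", "),
      paste(sprintf("%.2f", out$pca$proportion[out$pca$significant]),
            collapse = ", ")))
  }
  if (!is.null(out$regression)) {
    for (i in seq_len(nrow(out$regression$fit)))
      lines <- c(lines, sprintf(
        "Regression %s ~ axes: R^2 = %.2f, F p = %.3g.",
        out$regression$fit$metric[i], out$regression$fit$r_squared[i],
        out$regression$fit$f_p[i]))
  }
  lines
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(paste(pipeline_report(x), collapse = "\n"), "\n")
  invisible(x)
}
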