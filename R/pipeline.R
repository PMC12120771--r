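#' Validate a pipeline run configuration
#'
#' Flat key-value configuration (YAML file or R list). Unknown keys are
#' rejected so typos fail before any computation; every numeric field is
#' range-checked.
#'
#' @param config named list, or path to a YAML file.
#' @return validated config list with defaults filled in.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  known <- c("matrix", "catalog", "labels", "out_dir", "theta", "trim",
             "theta_sel", "log2_transform", "panels", "run_gsea",
             "gsea_nperm", "gsea_seed", "seed")
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  defaults <- list(theta = 0.2, trim = 0.2, theta_sel = 0,
                   log2_transform = TRUE, panels = default_panels(),
                   run_gsea = FALSE, gsea_nperm = 1000, gsea_seed = 17,
                   labels = NULL, catalog = NULL)
  for (k in names(defaults))
    if (is.null(config[[k]])) config[k] <- defaults[k]
  for (k in c("matrix", "out_dir"))
    if (is.null(config[[k]]))
      stop("missing required config key: ", k)
  num_ok <- function(key, ok)
    if (!is.numeric(config[[key]]) || length(config[[key]]) != 1L ||
        !is.finite(config[[key]]) || !ok(config[[key]]))
      stop("invalid config value for key: ", key)
  num_ok("theta", function(v) v > 0)
  num_ok("trim", function(v) v >= 0 && v < 1)
  num_ok("theta_sel", function(v) TRUE)
  num_ok("gsea_nperm", function(v) v >= 10)
  if (!is.list(config$panels) ||
      !all(c("ar_axis", "ne_axis") %in% names(config$panels)))
    stop("invalid config value for key: panels")
  config
}

write_tsv_with_header <- function(df, path, params = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(params), con)
  suppressWarnings(utils::write.table(df, con, sep = "\t", quote = FALSE,
                                      row.names = FALSE, col.names = TRUE))
  invisible(path)
}

read_tsv_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Run the full lineage-TF pipeline
#'
#' Orchestrates select -> score -> classify (-> GSEA) from a validated
#' configuration, writing TSV outputs with provenance headers (package
#' version, resolved parameters, input checksums). The composition equals
#' calling the stage functions individually with the same parameters — there
#' is no hidden state.
#'
#' @param config named list or YAML path; see [validate_config()] for keys.
#'   Required: \code{matrix}, \code{out_dir}. Optional: \code{catalog},
#'   \code{labels} (two-column or CLS file; panel selection when absent),
#'   \code{theta}, \code{trim}, \code{theta_sel}, \code{log2_transform},
#'   \code{panels}, \code{run_gsea}, \code{gsea_nperm}, \code{gsea_seed}.
#' @return invisibly, named character vector of output file paths.
#' @export
run_pipeline <- function(config) {
  cfg <- validate_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  inputs <- c(matrix = cfg$matrix, catalog = cfg$catalog, labels = cfg$labels)
  checks <- vapply(inputs, function(p) unname(tools::md5sum(p)), "")
  prov <- c(cfg[c("theta", "trim", "theta_sel", "log2_transform")],
            stats::setNames(as.list(checks), paste0("md5.", names(checks))))

  m <- read_expression_matrix(cfg$matrix)
  message("pipeline: read matrix ", nrow(m), " genes x ", ncol(m), " samples")
  labels <- if (!is.null(cfg$labels))
    read_labels(cfg$labels, sample_ids = colnames(m)) else NULL
  fit <- lineage_tf(m, labels = labels, catalog = cfg$catalog,
                    theta = cfg$theta, trim = cfg$trim,
                    log2_transform = cfg$log2_transform,
                    panels = lapply(cfg$panels, unlist),
                    theta_sel = cfg$theta_sel)
  n_lab <- table(factor(fit$labels, c("ADENO", "NEPC", "EXCLUDED")))
  message("pipeline: samples ADENO=", n_lab[["ADENO"]],
          " NEPC=", n_lab[["NEPC"]], " EXCLUDED=", n_lab[["EXCLUDED"]])

  out <- c(labels = file.path(cfg$out_dir, "labels.tsv"),
           scores = file.path(cfg$out_dir, "scores.tsv"),
           classes = file.path(cfg$out_dir, "classes.tsv"),
           sets = file.path(cfg$out_dir, "sets.gmt"))
  write_tsv_with_header(data.frame(sample = names(fit$labels),
                                   group = unname(fit$labels)),
                        out[["labels"]], prov)
  write_tsv_with_header(
    fit$scores[, c("tf", "Z_ad", "Z_NE", "n_ad", "n_NE", "k_ad", "k_NE")],
    out[["scores"]], prov)
  write_tsv_with_header(fit$scores[, c("tf", "category", "Z_ad", "Z_NE")],
                        out[["classes"]], prov)
  write_gmt(lapply(stats::setNames(nm = c("SHARED", "AD", "NE")), function(g)
    list(name = paste0(g, "_TFS"), description = "tflens",
         members = fit$sets[[g]])), out[["sets"]])
  cnt <- attr(fit$scores, "counts")
  message("pipeline: sets SHARED=", cnt[["SHARED"]], " AD=", cnt[["AD"]],
          " NE=", cnt[["NE"]])

  if (isTRUE(cfg$run_gsea)) {
    sets <- Filter(length, fit$sets)
    res <- gsea(m, fit$labels, sets, n_perm = cfg$gsea_nperm,
                seed = cfg$gsea_seed, groups = c("ADENO", "NEPC"))
    out <- c(out, gsea = file.path(cfg$out_dir, "gsea.tsv"))
    write_tsv_with_header(res, out[["gsea"]], prov)
    message("pipeline: GSEA on ", nrow(res), " sets (n_perm=",
            cfg$gsea_nperm, ")")
  }
  invisible(out)
}
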