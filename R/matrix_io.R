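#' Normalize gene symbols
#'
#' Canonicalizes gene symbols: strips surrounding whitespace and upper-cases.
#' Hyphenated symbols (e.g. \code{NKX3-1}) are kept verbatim; no alias-database
#' resolution is attempted, so symbol handling is deterministic and offline.
#'
#' @param x character vector of gene symbols.
#' @return character vector of canonical symbols.
#' @export
#' @examples
#' normalize_symbols(c(" ar ", "nkx3-1"))
normalize_symbols <- function(x) {
  toupper(trimws(as.character(x)))
}

#' Read a gene-by-sample expression matrix
#'
#' Reads a delimited text matrix whose first row holds sample identifiers and
#' whose first column holds gene symbols. Symbols are canonicalized with
#' [normalize_symbols()]; duplicate gene rows (after canonicalization) are
#' collapsed by their arithmetic mean with a warning. Lines starting with
#' \code{#} are ignored, so files written by [write_expression_matrix()]
#' round-trip.
#'
#' @param path path to the file.
#' @param dialect \code{"tsv"} (default) or \code{"csv"}.
#' @param transpose logical; set \code{TRUE} when the file stores samples in
#'   rows and genes in columns.
#' @return numeric matrix (genes in rows, samples in columns) with attribute
#'   \code{"read_report"}: a list with \code{n_genes}, \code{n_samples} and
#'   \code{n_duplicates_collapsed}.
#' @export
read_expression_matrix <- function(path, dialect = c("tsv", "csv"),
                                   transpose = FALSE) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tsv") "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                          check.names = FALSE, row.names = NULL,
                          stringsAsFactors = FALSE, quote = "")
  if (nrow(df) == 0L || ncol(df) < 2L)
    stop("empty expression matrix in '", path, "'")
  genes <- normalize_symbols(df[[1L]])
  samples <- trimws(colnames(df)[-1L])  # before [.data.frame de-duplicates
  if (anyDuplicated(samples))
    stop("duplicate sample id(s): ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  body <- df[, -1L, drop = FALSE]
  for (j in seq_along(body)) {
    col <- body[[j]]
    if (!is.numeric(col)) {
      suppressWarnings(num <- as.numeric(col))
      bad <- which(is.na(num) & !is.na(col) & nzchar(trimws(col)))
      if (length(bad))
        stop("non-numeric value '", col[bad[1L]], "' at gene '",
             genes[bad[1L]], "', sample '", samples[j], "'")
      body[[j]] <- num
    }
  }
  m <- as.matrix(body)
  if (!all(is.finite(m)))
    stop("non-finite value(s) in expression matrix '", path, "'")
  rownames(m) <- genes
  colnames(m) <- samples
  if (transpose) m <- t(m)
  n_dup <- sum(duplicated(rownames(m)))
  if (n_dup > 0L) {
    warning(n_dup, " duplicate gene row(s) collapsed by mean")
    m <- rowsum(m, group = rownames(m), reorder = FALSE) /
      as.vector(table(rownames(m))[unique(rownames(m))])
  }
  attr(m, "read_report") <- list(n_genes = nrow(m), n_samples = ncol(m),
                                 n_duplicates_collapsed = n_dup)
  m
}

#' Write an expression (or score) matrix as delimited text
#'
#' Writes a genes-in-rows matrix with a commented provenance header recording
#' the package version and any supplied parameters; [read_expression_matrix()]
#' skips those lines.
#'
#' @param m numeric matrix with gene rownames and sample colnames.
#' @param path output path.
#' @param dialect \code{"tsv"} or \code{"csv"}.
#' @param params named list recorded in the \code{#}-comment header.
#' @return invisibly, \code{path}.
#' @export
write_expression_matrix <- function(m, path, dialect = c("tsv", "csv"),
                                    params = list()) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tsv") "\t" else ","
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(params), con)
  writeLines(paste(c("gene", colnames(m)), collapse = sep), con)
  utils::write.table(data.frame(gene = rownames(m), m, check.names = FALSE),
                     con, sep = sep, quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

provenance_header <- function(params = list()) {
  kv <- if (length(params))
    paste(names(params), vapply(params, function(p)
      paste(format(p), collapse = ","), ""), sep = "=", collapse = "; ")
  else ""
  paste0("# tflens ",
         as.character(utils::packageVersion("tflens")),
         if (nzchar(kv)) paste0("; ", kv))
}

#' Read a TF catalog (plain gene-symbol list)
#'
#' One symbol per line; blank lines and \code{#} comments are skipped.
#' Symbols are canonicalized and de-duplicated (input order kept, warning on
#' duplicates).
#'
#' @param path path to the list file.
#' @return character vector of unique canonical symbols with attribute
#'   \code{"source_label"} (the file path).
#' @export
read_catalog <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  syms <- normalize_symbols(lines[nzchar(trimws(lines))])
  if (length(syms) == 0L) stop("empty catalog file '", path, "'")
  if (anyDuplicated(syms)) {
    warning(sum(duplicated(syms)), " duplicate symbol(s) dropped from catalog")
    syms <- syms[!duplicated(syms)]
  }
  structure(syms, source_label = path)
}

#' Read / write gene sets in GMT format
#'
#' GMT is the tab-separated gene-set container used by GSEA: one set per line,
#' \code{name TAB description TAB member TAB member ...}.
#'
#' @param path path to the GMT file.
#' @return for \code{read_gmt}, a named list of gene sets; each element is a
#'   list with \code{name}, \code{description} and \code{members} (unique
#'   canonical symbols, order preserved).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty GMT file '", path, "'")
  sets <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    f <- f[nzchar(f) | seq_along(f) <= 2L]
    if (length(f) < 3L)
      stop("GMT line ", i, ": fewer than 3 fields (need name, description, ",
           "and at least one member)")
    members <- unique(normalize_symbols(f[-(1:2)]))
    sets[[i]] <- list(name = f[1L], description = f[2L], members = members)
  }
  names(sets) <- vapply(sets, `[[`, "", "name")
  sets
}

#' @rdname read_gmt
#' @param sets named list of gene sets as returned by \code{read_gmt}, or a
#'   named list of plain character vectors.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(seq_along(sets), function(i) {
    s <- sets[[i]]
    if (is.character(s))
      s <- list(name = names(sets)[i], description = "na", members = s)
    paste(c(s$name, s$description, s$members), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read phenotype labels (CLS or two-column table)
#'
#' Supports the GSEA CLS categorical dialect (header \code{n_samples n_classes
#' 1}, a \code{#}-prefixed class-name line, then one label per sample) and a
#' headerless two-column \code{sample TAB group} table. CLS files carry no
#' sample ids, so ids must be supplied via \code{sample_ids} (usually the
#' matrix colnames, in file order).
#'
#' @param path path to the labels file.
#' @param dialect \code{"auto"} (sniff), \code{"cls"} or \code{"two_column"}.
#' @param sample_ids sample identifiers for CLS input, in column order.
#' @return named character vector mapping sample id to group, with attribute
#'   \code{"groups"} holding the declared group names in order.
#' @export
read_labels <- function(path, dialect = c("auto", "cls", "two_column"),
                        sample_ids = NULL) {
  dialect <- match.arg(dialect)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (dialect == "auto")
    dialect <- if (length(lines) >= 2L && startsWith(trimws(lines[2L]), "#"))
      "cls" else "two_column"
  if (dialect == "cls") {
    hdr <- as.integer(strsplit(trimws(lines[1L]), "[ \t]+")[[1L]])
    if (length(hdr) < 2L || anyNA(hdr))
      stop("malformed CLS header: '", lines[1L], "'")
    n_samp <- hdr[1L]; n_cls <- hdr[2L]
    groups <- strsplit(sub("^#[ \t]*", "", trimws(lines[2L])), "[ \t]+")[[1L]]
    if (length(groups) != n_cls)
      stop("CLS declares ", n_cls, " classes but names ", length(groups))
    lab <- unlist(strsplit(trimws(lines[-(1:2)]), "[ \t]+"))
    if (length(lab) != n_samp)
      stop("CLS declares ", n_samp, " samples but lists ", length(lab))
    # numeric labels index the class-name line (0-based), per the CLS dialect
    if (all(grepl("^[0-9]+$", lab))) lab <- groups[as.integer(lab) + 1L]
    if (!all(lab %in% groups))
      stop("CLS label(s) not among declared classes: ",
           paste(setdiff(lab, groups), collapse = ", "))
    if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(n_samp))
    if (length(sample_ids) != n_samp)
      stop("CLS declares ", n_samp, " samples but ", length(sample_ids),
           " sample_ids supplied")
    structure(stats::setNames(lab, sample_ids), groups = groups)
  } else {
    lines <- lines[!startsWith(trimws(lines), "#")]
    # tolerate an optional "sample group" header line
    first <- tolower(strsplit(trimws(lines[1L]), "[\t ]+")[[1L]])
    if (identical(first, c("sample", "group"))) lines <- lines[-1L]
    parts <- strsplit(trimws(lines), "[\t]|[ ]{2,}|[ ]")
    if (any(lengths(parts) < 2L))
      stop("two-column labels: line without a group field")
    ids <- vapply(parts, `[[`, "", 1L)
    grp <- vapply(parts, `[[`, "", 2L)
    if (anyDuplicated(ids))
      stop("duplicate sample id(s) in labels: ",
           paste(unique(ids[duplicated(ids)]), collapse = ", "))
    structure(stats::setNames(grp, ids), groups = unique(grp))
  }
}

#' Subset an expression matrix to a TF catalog
#'
#' Keeps exactly the catalog genes present in the matrix, in catalog order,
#' and reports catalog symbols absent from the matrix.
#'
#' @param m expression matrix (genes in rows).
#' @param catalog character vector of canonical symbols (see [read_catalog()]).
#' @return list with \code{matrix} (the subset) and \code{missing} (catalog
#'   symbols not found).
#' @export
subset_by_catalog <- function(m, catalog) {
  catalog <- unique(normalize_symbols(catalog))
  hit <- catalog[catalog %in% rownames(m)]
  if (length(hit) == 0L) stop("catalog disjoint from matrix")
  list(matrix = m[hit, , drop = FALSE], missing = setdiff(catalog, hit))
}
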