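# shared test fixtures, all built in code

# random gene-by-sample matrix on the linear scale
random_matrix <- function(n_genes, n_samples, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(2^rnorm(n_genes * n_samples, 8, 1), n_genes, n_samples)
  dimnames(m) <- list(sprintf("G%03d", seq_len(n_genes)),
                      sprintf("S%02d", seq_len(n_samples)))
  m
}

write_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# independent Excel-TRIMMEAN oracle: sort, drop floor(n*trim/2) per end
trimmean_oracle <- function(x, trim_total = 0.2) {
  n <- length(x)
  k <- floor(n * trim_total / 2)
  mean(sort(x)[(k + 1):(n - k)])
}

# independent weighted-KS running-sum oracle, evaluated at every prefix
es_oracle <- function(genes, scores, members, p_weight) {
  hit <- genes %in% members
  n_hit <- sum(hit)
  nr <- sum(abs(scores[hit])^p_weight)
  running <- numeric(length(genes))
  acc <- 0
  for (i in seq_along(genes)) {
    acc <- acc + if (hit[i]) {
      if (nr > 0) abs(scores[i])^p_weight / nr else 1 / n_hit
    } else -1 / (length(genes) - n_hit)
    running[i] <- acc
  }
  running[which.max(abs(running))]
}

# labels helper
two_group_labels <- function(samples, n_a, groups = c("ADENO", "NEPC")) {
  structure(setNames(rep(groups, c(n_a, length(samples) - n_a)), samples),
            groups = groups)
}
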