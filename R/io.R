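#' Read a directed network from a TSV edge list
#'
#' Expects a tab-separated file with header `source<TAB>target` and an
#' optional third `sign` column (+1/-1; signs do not affect modularity and
#' are kept as an attribute). Lines starting with `#` are comments. Node
#' labels are mapped to dense indices in order of first appearance;
#' duplicate edges and malformed rows are rejected with the offending line
#' number.
#'
#' @param path file path.
#' @return A [grn_digraph()] with node `labels`.
#' @export
read_edge_list <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) < 1) stop("empty edge list: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- tolower(trimws(fields[[1]]))
  if (length(header) < 2 || header[1] != "source" || header[2] != "target")
    stop("expected header 'source<TAB>target[<TAB>sign]' in ", path)
  has_sign <- length(header) >= 3 && header[3] == "sign"
  fields <- fields[-1]
  lineno <- lineno[-1]
  if (length(fields) == 0) stop("edge list has a header but no edges: ", path)
  n_col <- 2L + has_sign
  src <- character(length(fields))
  tgt <- character(length(fields))
  sgn <- rep(1, length(fields))
  for (k in seq_along(fields)) {
    f <- trimws(fields[[k]])
    if (length(f) != n_col || any(!nzchar(f[1:2])))
      stop("malformed edge-list row at line ", lineno[k], " of ", path)
    src[k] <- f[1]
    tgt[k] <- f[2]
    if (has_sign) {
      s <- suppressWarnings(as.numeric(f[3]))
      if (is.na(s) || !(s %in% c(-1, 1)))
        stop("sign must be +1 or -1 at line ", lineno[k], " of ", path)
      sgn[k] <- s
    }
  }
  dup <- anyDuplicated(paste(src, tgt, sep = "\r"))
  if (dup) stop("duplicate edge '", src[dup], " -> ", tgt[dup],
                "' at line ", lineno[dup], " of ", path)
  labels <- unique(c(rbind(src, tgt)))  # first-appearance order
  g <- grn_digraph(length(labels),
                   cbind(match(src, labels), match(tgt, labels)),
                   labels = labels)
  attr(g, "signs") <- sgn
  g
}

#' Write a directed network as a TSV edge list
#'
#' Inverse of [read_edge_list()]; round-trips any `grn_digraph` losslessly
#' (up to node relabelling when the graph has no labels).
#'
#' @param graph a [grn_digraph()].
#' @param path output file path.
#' @export
write_edge_list <- function(graph, path) {
  graph <- as_digraph(graph)
  labels <- graph$labels %||% as.character(seq_len(graph$n_nodes))
  df <- data.frame(source = labels[graph$edges[, 1]],
                   target = labels[graph$edges[, 2]])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a genotype as a signed edge list
#'
#' Serializes a genotype matrix as a TSV of `source target weight` rows
#' (weight `g[target, source]`, 12 significant digits) preceded by comment
#' headers recording `n_genes` and the mode, so genes without interactions
#' survive the round trip.
#'
#' @param genotype a [grn_genotype()].
#' @param path output file path.
#' @export
write_genotype <- function(genotype, path) {
  g <- as_genotype_matrix(genotype)
  nz <- which(g != 0, arr.ind = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# n_genes: %d", nrow(g)),
               sprintf("# mode: %s", genotype_mode(genotype)),
               "source\ttarget\tweight"), con)
  if (nrow(nz) > 0) {
    writeLines(sprintf("%d\t%d\t%.12g", nz[, "col"], nz[, "row"],
                       g[nz]), con)
  }
  invisible(path)
}

#' Read a genotype written by [write_genotype()]
#'
#' @param path file path.
#' @return A [grn_genotype()].
#' @export
read_genotype <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  n_line <- grep("n_genes:", hdr, value = TRUE)
  if (length(n_line) != 1)
    stop("genotype file lacks the '# n_genes:' header: ", path)
  n <- as.integer(sub(".*n_genes:\\s*", "", n_line))
  mode_line <- grep("mode:", hdr, value = TRUE)
  mode <- if (length(mode_line) == 1) sub(".*mode:\\s*", "", mode_line)
          else "discrete"
  body <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(body) < 1 || !grepl("^source\ttarget\tweight$", body[1]))
    stop("expected header 'source<TAB>target<TAB>weight' in ", path)
  g <- matrix(0, n, n)
  if (length(body) > 1) {
    parts <- strsplit(body[-1], "\t", fixed = TRUE)
    bad <- which(lengths(parts) != 3)
    if (length(bad) > 0) stop("malformed genotype row in ", path)
    m <- matrix(as.numeric(unlist(parts)), ncol = 3, byrow = TRUE)
    if (anyNA(m)) stop("non-numeric genotype entry in ", path)
    if (any(m[, 1] < 1 | m[, 1] > n | m[, 2] < 1 | m[, 2] > n))
      stop("gene index out of range in ", path)
    if (anyDuplicated(m[, 1:2, drop = FALSE]))
      stop("duplicate interaction in ", path)
    g[cbind(m[, 2], m[, 1])] <- m[, 3]
  }
  grn_genotype(g, mode = match.arg(mode, c("discrete", "continuous")))
}
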