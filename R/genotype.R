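#' Construct a genotype matrix
#'
#' The genotype of a network of `N` cross-regulating genes is an `N x N`
#' signed matrix `G`. Row `i` lists the regulators of gene `i`: `g[i, j] > 0`
#' means gene `j` activates gene `i`, `g[i, j] < 0` means it inhibits it, and
#' `g[i, j] == 0` means no regulation. In `"discrete"` mode (the default
#' model) every nonzero entry is +1 or -1; in `"continuous"` mode entries are
#' arbitrary real regulatory weights (states remain binary in both modes).
#'
#' @param g square numeric matrix of regulatory effects.
#' @param mode `"discrete"` or `"continuous"`.
#' @return An object of class `grn_genotype` (a numeric matrix with a `mode`
#'   attribute).
#' @examples
#' g <- grn_genotype(rbind(c(0, 1), c(-1, 0)))
#' n_interactions(g)
#' @export
grn_genotype <- function(g, mode = c("discrete", "continuous")) {
  mode <- match.arg(mode)
  g <- as.matrix(g)
  if (nrow(g) != ncol(g)) stop("genotype matrix must be square")
  if (!is.numeric(g) || anyNA(g)) stop("genotype entries must be finite numbers")
  if (mode == "discrete" && !all(g %in% c(-1, 0, 1)))
    stop("discrete genotypes only admit entries -1, 0, +1")
  storage.mode(g) <- "double"
  dimnames(g) <- NULL
  structure(g, class = "grn_genotype", gmode = mode)
}

#' @export
print.grn_genotype <- function(x, ...) {
  cat(sprintf("<grn_genotype> %d genes, %d interactions (%s mode)\n",
              n_genes(x), n_interactions(x), genotype_mode(x)))
  print(unclass_genotype(x))
  invisible(x)
}

unclass_genotype <- function(g) {
  attr(g, "gmode") <- NULL
  unclass(g)
}

as_genotype_matrix <- function(genotype) {
  g <- as.matrix(genotype)
  if (nrow(g) != ncol(g)) stop("genotype matrix must be square")
  storage.mode(g) <- "double"
  attributes(g) <- list(dim = dim(g))  # bare matrix
  g
}

#' Number of genes in a genotype
#' @param genotype a [grn_genotype()] or plain square matrix.
#' @return Integer scalar.
#' @export
n_genes <- function(genotype) nrow(as_genotype_matrix(genotype))

#' Number of regulatory interactions (nonzero genotype entries)
#' @inheritParams n_genes
#' @return Integer scalar.
#' @export
n_interactions <- function(genotype) sum(as_genotype_matrix(genotype) != 0)

#' Genotype mode (`"discrete"` or `"continuous"`)
#' @inheritParams n_genes
#' @export
genotype_mode <- function(genotype) {
  m <- attr(genotype, "gmode")
  if (is.null(m)) if (all(genotype %in% c(-1, 0, 1))) "discrete" else "continuous"
  else m
}

#' Per-gene regulator counts
#'
#' The number of regulators of gene `i` is the number of nonzero entries of
#' row `i`. Mutation pulls this count towards `gamma * N`.
#' @inheritParams n_genes
#' @return Integer vector of length `N`.
#' @export
regulator_counts <- function(genotype) {
  rowSums(as_genotype_matrix(genotype) != 0)
}

#' Random genotype with a fixed number of interactions
#'
#' Places `n_interactions` regulatory interactions uniformly at random among
#' the `N^2` (or `N^2 - N` when self-regulation is forbidden) entries, with
#' independent equiprobable +1/-1 signs (discrete mode) or standard-normal
#' weights (continuous mode).
#'
#' @param n_genes number of genes `N`.
#' @param n_interactions number of nonzero entries to place.
#' @param mode `"discrete"` or `"continuous"`.
#' @param allow_self logical; permit self-regulation `g[i, i] != 0`?
#' @return A [grn_genotype()].
#' @export
random_genotype <- function(n_genes, n_interactions,
                            mode = c("discrete", "continuous"),
                            allow_self = TRUE) {
  mode <- match.arg(mode)
  positions <- if (allow_self) seq_len(n_genes^2)
               else which(diag(n_genes) == 0)
  if (n_interactions > length(positions))
    stop("more interactions requested than available matrix entries")
  g <- matrix(0, n_genes, n_genes)
  idx <- sample(positions, n_interactions)
  g[idx] <- if (mode == "discrete") sample(c(-1, 1), n_interactions, replace = TRUE)
            else stats::rnorm(n_interactions)
  grn_genotype(g, mode = mode)
}
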