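#' Spearman-correlation distance between compounds
#'
#' Compounds are compared by how their emissions co-vary across species:
#' species-mean profiles are the observations, Spearman rank correlation
#' (ties mid-ranked) the similarity, and \code{d = 1 - rho} the distance.
#' Constant compounds, whose correlation is undefined, are assigned
#' \code{rho = 0} against everything.
#'
#' @param matrix An \code{emission_matrix} with >= 3 species.
#' @return Symmetric compound x compound distance matrix (zero diagonal).
#' @export
spearman_distance_matrix <- function(matrix) {
  st <- sample_table(matrix)
  sp <- unique(st$species_id)
  if (length(sp) < 3) stop("need >= 3 species for compound clustering")
  means <- t(vapply(sp, function(s)
    colMeans(unclass(matrix)[st$species_id == s, , drop = FALSE]),
    numeric(ncol(matrix))))
  colnames(means) <- colnames(matrix)
  rho <- suppressWarnings(cor(means, method = "spearman"))
  rho[!is.finite(rho)] <- 0
  d <- 1 - rho
  diag(d) <- 0
  d
}

#' Cluster compounds and assign letters
#'
#' Agglomerative hierarchical clustering (average linkage by default, i.e.
#' UPGMA; complete linkage available) of the Spearman distance matrix, cut
#' into exactly \code{k} clusters. Letters are assigned to clusters in
#' dendrogram leaf order starting at "A" (then "AA", "AB", ... beyond 26).
#'
#' @param distances Distance matrix from [spearman_distance_matrix()].
#' @param k Number of clusters (default 17).
#' @param linkage "average" or "complete".
#' @return List of class \code{cluster_assignment}: \code{letters} (named
#'   character vector compound -> letter), \code{tree} (the \code{hclust}
#'   object), \code{k}.
#' @export
cluster_compounds <- function(distances, k = 17, linkage = c("average", "complete")) {
  linkage <- match.arg(linkage)
  p <- nrow(distances)
  if (k > p) stop(sprintf("k = %d exceeds the number of compounds (%d)", k, p))
  if (k < 1) stop("k must be >= 1")
  tree <- hclust(as.dist(distances), method = linkage)
  memb <- cutree(tree, k = k)
  # letter clusters by order of first appearance along the dendrogram leaves
  first_seen <- unique(memb[tree$order])
  lab <- cluster_letters(k)
  letters_out <- setNames(lab[match(memb, first_seen)], names(memb))
  structure(list(letters = letters_out, tree = tree, k = k),
            class = "cluster_assignment")
}

cluster_letters <- function(k) {
  if (k <= 26) return(LETTERS[seq_len(k)])
  c(LETTERS, as.vector(t(outer(LETTERS, LETTERS, paste0))))[seq_len(k)]
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("cluster_assignment: %d compounds in %d clusters (%s)\n",
              length(x$letters), x$k,
              paste(head(unique(x$letters[x$tree$order]), 8), collapse = " ")))
  invisible(x)
}
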