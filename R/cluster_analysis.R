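# Geometric cluster identification: the droplet/aggregate size N_D.

#' Find geometric clusters and the largest droplet size
#'
#' Builds a graph on constituents: particles are adjacent iff their
#' minimum-image distance is at most `r_cl` (boundary inclusive); polymer
#' chains are adjacent iff any inter-chain monomer pair is within `r_cl`.
#' Connected components are the clusters; `n_d` is the size of the largest
#' one, the droplet/aggregate size used as reaction coordinate.
#'
#' The default cutoff is the LJ interaction cutoff \eqn{r_c = 2.5\sigma},
#' the natural connectivity scale of the truncated potential; it is a
#' tunable parameter because the droplet size definition is a convention.
#'
#' @param cfg a [configuration()] or coordinate matrix.
#' @param spec a [system_spec()].
#' @param r_cl cluster cutoff distance (> 0).
#' @return object of class `cluster_result`: `labels` (constituent to
#'   cluster id, ids numbered by first appearance), `sizes` (one per
#'   cluster) and `n_d = max(sizes)`.
#' @export
find_clusters <- function(cfg, spec, r_cl = spec$lj_cutoff) {
  stopifnot(r_cl > 0)
  pos <- if (inherits(cfg, "configuration")) cfg$positions else as.matrix(cfg)
  labels <- cpp_find_clusters(pos %% spec$box_length, spec_as_list(spec),
                              r_cl)
  sizes <- as.integer(table(labels))
  out <- list(labels = labels, sizes = sizes, n_d = max(sizes))
  class(out) <- "cluster_result"
  out
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("cluster_result: %d clusters, largest N_D = %d\n",
              length(x$sizes), x$n_d))
  invisible(x)
}
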