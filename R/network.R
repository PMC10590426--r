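#' Build a chromatin-interaction network from loop calls
#'
#' Nodes are the genomic bins appearing as loop anchors; one undirected edge
#' joins the two anchors of each unique loop, carrying its genomic
#' separation in bp. Edges are cis-only by construction of the [loop_list].
#'
#' @param loops a [loop_list].
#' @param bins a [genomic_bins] object.
#' @return A `chromatin_network` with fields `nodes` (arm, bin), `edges`
#'   (arm, bin1, bin2, sep_bp), `tracks` (genome-wide feature annotations,
#'   see [annotate_nodes]) and `bins`.
#' @export
build_network <- function(loops, bins) {
  stopifnot(inherits(loops, "loop_list"), inherits(bins, "genomic_bins"))
  if (nrow(loops) == 0L) warning("empty loop list: network has no edges")
  edges <- data.frame(arm = loops$arm, bin1 = loops$bin1, bin2 = loops$bin2,
                      sep_bp = (loops$bin2 - loops$bin1) * bins$bin_size,
                      stringsAsFactors = FALSE)
  nodes <- data.frame(arm = c(edges$arm, edges$arm),
                      bin = c(edges$bin1, edges$bin2),
                      stringsAsFactors = FALSE)
  nodes <- nodes[!duplicated(paste(nodes$arm, nodes$bin)), , drop = FALSE]
  nodes <- nodes[order(nodes$arm, nodes$bin), , drop = FALSE]
  rownames(nodes) <- NULL
  structure(list(nodes = nodes, edges = edges, tracks = list(), bins = bins),
            class = "chromatin_network")
}

#' @export
print.chromatin_network <- function(x, ...) {
  cat("chromatin_network:", nrow(x$nodes), "nodes,", nrow(x$edges),
      "edges, features:", paste(names(x$tracks), collapse = ", "), "\n")
  invisible(x)
}

#' Genome-wide feature track from a peak set
#'
#' Computes one value per bin over every arm. In binary mode a bin scores 1
#' iff it overlaps any peak by at least 1 bp; in signal mode each peak
#' contributes `signal * overlap_bp / peak_width` to every bin it overlaps
#' (so a peak's contributions sum to its signal).
#'
#' @param bins a [genomic_bins] object.
#' @param peaks a [peak_set].
#' @param mode `"binary"` or `"signal"`.
#' @return Named list (per arm) of numeric vectors of length `n_bins`.
#' @export
feature_track <- function(bins, peaks, mode = c("binary", "signal")) {
  mode <- match.arg(mode)
  if (mode == "signal" && !("signal" %in% names(peaks)))
    stop("signal mode requires a signal column")
  track <- lapply(bins$n_bins, function(n) numeric(n))
  bs <- bins$bin_size
  for (i in seq_len(nrow(peaks))) {
    arm <- peaks$arm[i]
    if (!arm %in% bins$arms) stop("peak on unknown arm: ", arm)
    s <- peaks$start[i]; e <- peaks$end[i]
    b0 <- max(0L, as.integer(s %/% bs))
    b1 <- min(bins$n_bins[[arm]] - 1L, as.integer((e - 1L) %/% bs))
    if (b1 < b0) next
    bb <- b0:b1
    if (mode == "binary") {
      track[[arm]][bb + 1L] <- 1
    } else {
      ov <- pmin(e, (bb + 1) * bs) - pmax(s, bb * bs)
      track[[arm]][bb + 1L] <- track[[arm]][bb + 1L] +
        peaks$signal[i] * ov / (e - s)
    }
  }
  track
}

#' Annotate network nodes with a feature
#'
#' The feature is stored as a genome-wide per-bin track (not just on current
#' nodes) so that distance-preserving randomizations, whose edges land on
#' arbitrary bins, can look feature values up at the new positions.
#'
#' @param network a `chromatin_network`.
#' @param peaks a [peak_set], or a precomputed track (named per-arm list of
#'   per-bin numeric vectors).
#' @param name feature name under which the track is stored.
#' @param mode `"binary"` (1 iff >= 1 bp peak overlap) or `"signal"`.
#' @return The network with the track added.
#' @export
annotate_nodes <- function(network, peaks, name, mode = c("binary", "signal")) {
  stopifnot(inherits(network, "chromatin_network"))
  if (inherits(peaks, "peak_set")) {
    mode <- match.arg(mode)
    track <- feature_track(network$bins, peaks, mode)
  } else if (is.list(peaks)) {
    track <- peaks
    if (!all(network$bins$arms %in% names(track)))
      stop("precomputed track must cover every arm")
  } else stop("peaks must be a peak_set or a per-arm track list")
  network$tracks[[name]] <- track
  network
}

#' Feature values at the network's nodes
#'
#' @param network an annotated `chromatin_network`.
#' @param feature feature name.
#' @return Numeric vector aligned to `network$nodes`.
#' @export
node_values <- function(network, feature) {
  tr <- network$tracks[[feature]]
  if (is.null(tr)) stop("feature not annotated: ", feature)
  mapply(function(a, b) tr[[a]][b + 1L], network$nodes$arm, network$nodes$bin,
         USE.NAMES = FALSE)
}

# track values at edge endpoints -> list(v1, v2)
.edge_values <- function(network, feature) {
  tr <- network$tracks[[feature]]
  if (is.null(tr)) stop("feature not annotated: ", feature)
  look <- function(arm, bin) {
    v <- numeric(length(arm))
    for (a in unique(arm)) {
      sel <- arm == a
      v[sel] <- tr[[a]][bin[sel] + 1L]
    }
    v
  }
  list(v1 = look(network$edges$arm, network$edges$bin1),
       v2 = look(network$edges$arm, network$edges$bin2))
}

# symmetrized endpoint-pair Pearson over both edge orientations;
# NA (undefined) when either endpoint vector has zero variance
.endpoint_pearson <- function(a1, a2, b1, b2) {
  x <- c(a1, a2); y <- c(b2, b1)
  if (length(x) < 2L) return(NA_real_)
  if (stats::var(x) == 0 || stats::var(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' Chromatin assortativity (ChAs) of a node feature
#'
#' Assortativity measures the preference of network nodes to connect to
#' nodes carrying the same feature. It is computed as the Pearson
#' correlation of feature values across edge endpoints, over the directed
#' edge list containing each undirected edge in both orientations, which
#' makes the value symmetric and equal to Newman's scalar assortativity
#' coefficient. A feature that is constant on all edge endpoints has zero
#' variance and its assortativity is undefined, returned as `NA` (never
#' silently 0).
#'
#' @param network an annotated `chromatin_network` with >= 2 edges.
#' @param feature feature name.
#' @return Assortativity in \[-1, 1\], or `NA` when undefined.
#' @export
chas <- function(network, feature) {
  if (nrow(network$edges) < 2L) stop("need >= 2 edges")
  ev <- .edge_values(network, feature)
  .endpoint_pearson(ev$v1, ev$v2, ev$v1, ev$v2)
}

#' Cross-assortativity of two features (cross-ChAs)
#'
#' Pearson correlation between feature A at one end of each edge and
#' feature B at the other end, symmetrized over both orientations; measures
#' whether regions bound by one factor preferentially contact regions bound
#' by the other. `cross_chas(net, f, f)` equals `chas(net, f)`.
#'
#' @inheritParams chas
#' @param featureA,featureB feature names.
#' @return Symmetrized cross-assortativity, or `NA` when undefined.
#' @export
cross_chas <- function(network, featureA, featureB) {
  if (nrow(network$edges) < 2L) stop("need >= 2 edges")
  a <- .edge_values(network, featureA)
  b <- .edge_values(network, featureB)
  .endpoint_pearson(a$v1, a$v2, b$v1, b$v2)
}

#' Co-occupancy assortativity of two features (AND-ChAs)
#'
#' Assortativity of the derived binary feature that marks nodes where both
#' features are nonzero, measuring whether co-occupied regions
#' preferentially contact each other.
#'
#' @inheritParams cross_chas
#' @return AND-assortativity, or `NA` when undefined (e.g. the features
#'   never co-occur).
#' @export
and_chas <- function(network, featureA, featureB) {
  network <- .with_and_track(network, featureA, featureB)
  chas(network, ".and.")
}

.with_and_track <- function(network, featureA, featureB) {
  ta <- network$tracks[[featureA]]; tb <- network$tracks[[featureB]]
  if (is.null(ta) || is.null(tb)) stop("both features must be annotated")
  network$tracks[[".and."]] <- mapply(function(a, b) as.numeric(a != 0 & b != 0),
                                      ta, tb, SIMPLIFY = FALSE)
  network
}

# draw new edge start bins uniformly per arm at exact separation;
# returns integer start bins (0-based)
.sample_edge_starts <- function(edges, bins) {
  sb <- (edges$bin2 - edges$bin1)
  max_start <- bins$n_bins[edges$arm] - 1L - sb
  if (any(max_start < 0L))
    stop("edge separation longer than its arm")
  st <- as.integer(floor(stats::runif(nrow(edges)) * (max_start + 1)))
  pmin(st, max_start)
}

# one distance-preserving randomization of the edge table; duplicate edges
# are resampled (up to max_tries), then kept with a count attribute
.randomize_edges <- function(edges, bins, max_tries = 1000L) {
  sb <- edges$bin2 - edges$bin1
  st <- .sample_edge_starts(edges, bins)
  key <- paste(edges$arm, st, sb)
  tries <- 0L
  repeat {
    dup <- duplicated(key)
    if (!any(dup) || tries >= max_tries) break
    st[dup] <- .sample_edge_starts(edges[dup, , drop = FALSE], bins)
    key[dup] <- paste(edges$arm[dup], st[dup], sb[dup])
    tries <- tries + 1L
  }
  out <- data.frame(arm = edges$arm, bin1 = st, bin2 = st + sb,
                    sep_bp = edges$sep_bp, stringsAsFactors = FALSE)
  attr(out, "n_duplicates_kept") <- sum(duplicated(key))
  out
}

#' Distance-preserving network randomization
#'
#' Each edge is replaced by an edge of identical genomic separation at a
#' uniformly sampled position on the same arm, so that the multiset of
#' (arm, separation) over edges is preserved exactly. This is the null
#' model against which assortativity is standardized: it keeps the trivial
#' assortativity that linear co-occurrence of a feature along the genome
#' would produce, while destroying 3D specificity. Duplicate randomized
#' edges are resampled (up to 1000 rounds, then kept with a logged count).
#' Node features are looked up genome-wide at the new positions.
#'
#' @param network a nonempty `chromatin_network`.
#' @param seed integer seed (`NULL` to use the current RNG state).
#' @return A randomized `chromatin_network` with the same tracks.
#' @export
randomize_network <- function(network, seed = NULL) {
  stopifnot(inherits(network, "chromatin_network"))
  if (nrow(network$edges) == 0L) stop("cannot randomize an empty network")
  if (!is.null(seed)) set.seed(seed)
  redges <- .randomize_edges(network$edges, network$bins)
  n_dup <- attr(redges, "n_duplicates_kept")
  if (n_dup > 0L) message("kept ", n_dup, " duplicate randomized edge(s)")
  nodes <- data.frame(arm = c(redges$arm, redges$arm),
                      bin = c(redges$bin1, redges$bin2),
                      stringsAsFactors = FALSE)
  nodes <- nodes[!duplicated(paste(nodes$arm, nodes$bin)), , drop = FALSE]
  nodes <- nodes[order(nodes$arm, nodes$bin), , drop = FALSE]
  rownames(nodes) <- NULL
  out <- network
  out$nodes <- nodes
  out$edges <- redges
  out
}

#' Assortativity Z-score against the distance-preserving null
#'
#' Standardizes the observed assortativity X against `n_rand`
#' randomizations: `z = (X - mu) / sigma`, where mu and sigma are the mean
#' and sample standard deviation of the randomized assortativities.
#' Randomizations with undefined assortativity are dropped and the
#' effective count reported; more than 50% undefined is an error (the
#' network is too small or the feature too sparse). A Z-score above 2 is
#' the conventional significance threshold for preferential 3D contact.
#'
#' @param network an annotated `chromatin_network`.
#' @param feature feature name (for `mode = "cross"`/`"and"`, the first
#'   feature).
#' @param n_rand number of randomizations (default 1000).
#' @param seed integer seed; results are deterministic per seed.
#' @param mode `"plain"`, `"cross"` or `"and"`.
#' @param featureB second feature for cross/and modes.
#' @return A `chas_result` with fields `feature`, `mode`, `X`, `mu`,
#'   `sigma`, `z`, `n_rand`, `n_rand_effective`.
#' @export
chas_zscore <- function(network, feature, n_rand = 1000, seed = 1,
                        mode = c("plain", "cross", "and"), featureB = NULL) {
  mode <- match.arg(mode)
  if (mode != "plain" && is.null(featureB))
    stop("featureB required for mode ", mode)
  if (mode == "and") {
    network <- .with_and_track(network, feature, featureB)
    featA <- ".and."; featB <- ".and."
  } else {
    featA <- feature
    featB <- if (mode == "cross") featureB else feature
  }
  X <- if (mode == "cross") cross_chas(network, featA, featB)
       else chas(network, featA)
  if (is.na(X)) stop("observed assortativity is undefined for this feature")
  if (!is.null(seed)) set.seed(seed)
  bins <- network$bins
  ta <- network$tracks[[featA]]; tb <- network$tracks[[featB]]
  # concatenated tracks with per-arm offsets for O(1) lookup
  offs <- c(0L, cumsum(bins$n_bins))[seq_along(bins$arms)]
  names(offs) <- bins$arms
  flat_a <- unlist(ta[bins$arms], use.names = FALSE)
  flat_b <- unlist(tb[bins$arms], use.names = FALSE)
  edges <- network$edges
  off_e <- offs[edges$arm]
  sb <- edges$bin2 - edges$bin1
  vals <- numeric(n_rand)
  for (r in seq_len(n_rand)) {
    re <- .randomize_edges(edges, bins)
    i1 <- off_e + re$bin1 + 1L
    i2 <- off_e + re$bin2 + 1L
    vals[r] <- .endpoint_pearson(flat_a[i1], flat_a[i2], flat_b[i1], flat_b[i2])
  }
  ok <- !is.na(vals)
  if (mean(ok) < 0.5)
    stop("more than 50% of randomizations undefined; use a larger network")
  mu <- mean(vals[ok])
  sigma <- stats::sd(vals[ok])
  z <- if (sigma > 0) (X - mu) / sigma else NA_real_
  structure(list(feature = feature, featureB = featureB, mode = mode,
                 X = X, mu = mu, sigma = sigma, z = z,
                 n_rand = n_rand, n_rand_effective = sum(ok),
                 rand_values = vals[ok]),
            class = "chas_result")
}

#' @export
print.chas_result <- function(x, ...) {
  cat(sprintf("ChAs [%s] %s: X = %.4f, mu = %.4f, sigma = %.4f, z = %.2f (n_rand = %d effective)\n",
              x$mode, x$feature, x$X, x$mu, x$sigma, x$z, x$n_rand_effective))
  invisible(x)
}

#' Write a network as edge-list and node-feature tables
#'
#' @param network a `chromatin_network`.
#' @param edge_path TSV path for edges (arm, bin1, bin2, sep_bp).
#' @param node_path optional TSV path for node features.
#' @return `edge_path`, invisibly.
#' @export
write_network <- function(network, edge_path, node_path = NULL) {
  utils::write.table(network$edges, edge_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(node_path)) {
    nd <- network$nodes
    for (f in names(network$tracks))
      if (f != ".and.") nd[[f]] <- node_values(network, f)
    utils::write.table(nd, node_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(edge_path)
}
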