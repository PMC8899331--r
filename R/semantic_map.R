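#' Classical (Torgerson) multidimensional scaling
#'
#' Double-centers the squared distance matrix, eigendecomposes it, and keeps
#' the smallest number of leading dimensions whose positive-eigenvalue mass
#' reaches `variance_threshold` (capped at `max_dims`). Variance explained is
#' computed over positive eigenvalues only; negative eigenvalues (which arise
#' for non-Euclidean dissimilarities such as cosine distances) are kept in
#' the result as a diagnostic.
#'
#' @param D symmetric distance matrix with item dimnames (see
#'   [validate_distance_matrix]).
#' @param variance_threshold fraction of (positive-eigenvalue) variance to
#'   retain, in `(0, 1]`. Default 0.96.
#' @param max_dims cap on the number of retained dimensions. Default 50.
#' @return object of class `mds_result`: `items`, `coordinates` (m x k),
#'   `eigenvalues` (all m, non-increasing), `k_selected`,
#'   `variance_explained`, `negative_eigenvalue_mass`.
#' @export
classical_mds <- function(D, variance_threshold = 0.96, max_dims = 50L) {
  validate_distance_matrix(D, tol = 1e-6, max_value = Inf)
  if (!(variance_threshold > 0 && variance_threshold <= 1))
    stop("variance_threshold must be in (0, 1]")
  m <- nrow(D)
  if (m < 2L) stop("need at least 2 items")
  J <- diag(m) - matrix(1 / m, m, m)
  B <- -0.5 * J %*% (D^2) %*% J
  B <- (B + t(B)) / 2
  eg <- eigen(B, symmetric = TRUE)
  ev <- eg$values
  tol <- max(abs(ev)) * 1e-10
  pos <- ev > tol
  if (!any(pos))
    stop("no positive eigenvalue: distance matrix is degenerate ",
         "(identical points?) or wholly non-Euclidean")
  pos_ev <- ev[pos]
  cum_frac <- cumsum(pos_ev) / sum(pos_ev)
  k_needed <- which(cum_frac >= variance_threshold - 1e-12)[1]
  k <- min(k_needed, max_dims, length(pos_ev), m - 1L)
  achieved <- cum_frac[k]
  if (achieved < variance_threshold - 1e-12)
    warning(sprintf(
      "variance threshold %.3f unattainable within max_dims = %d; achieved %.4f",
      variance_threshold, max_dims, achieved))
  coords <- eg$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(pos_ev[seq_len(k)]), k, k)
  rownames(coords) <- rownames(D)
  structure(list(items = rownames(D), coordinates = coords,
                 eigenvalues = ev, k_selected = k,
                 variance_explained = achieved,
                 negative_eigenvalue_mass = -sum(ev[ev < -tol])),
            class = "mds_result")
}

#' @export
print.mds_result <- function(x, ...) {
  cat(sprintf(
    "<mds_result: %d items, k = %d dims, %.2f%% variance explained>\n",
    length(x$items), x$k_selected, 100 * x$variance_explained))
  invisible(x)
}

#' Cumulative variance-explained profile of an MDS solution
#'
#' @param mds an `mds_result`.
#' @return numeric vector: fraction of positive-eigenvalue variance explained
#'   by the top `k` dimensions, for `k = 1 ... #positive eigenvalues`.
#' @export
mds_variance_profile <- function(mds) {
  ev <- mds$eigenvalues
  pos <- ev[ev > max(abs(ev)) * 1e-10]
  cumsum(pos) / sum(pos)
}

#' t-SNE embedding with restarts and minimum-KL selection
#'
#' Runs exact t-SNE (`Rtsne::Rtsne`, `theta = 0`) `n_restarts` times with
#' seeds `seed, seed + 1, ...` and returns the run with the lowest final
#' Kullback-Leibler divergence; every restart's KL is kept in the log.
#'
#' @param x an `mds_result` or a numeric coordinate matrix (rows = items).
#' @param perplexity effective number of nearest neighbors; 5-50 recommended
#'   (a warning is issued outside that band). Default 20.
#' @param n_iter gradient-descent iterations. Default 1500; values below 250
#'   warn (unstable embeddings).
#' @param n_restarts number of seeded restarts (>= 1). Default 10.
#' @param seed base RNG seed. Default 0.
#' @return object of class `semantic_map`: `items`, `coords2d` (m x 2),
#'   `kl_divergence`, `perplexity`, `n_iter`, `seed` (seed of the winning
#'   run), `n_restarts`, `restart_log` (data frame seed/kl).
#' @export
embed_tsne <- function(x, perplexity = 20, n_iter = 1500L,
                       n_restarts = 10L, seed = 0L) {
  X <- if (inherits(x, "mds_result")) x$coordinates else as.matrix(x)
  m <- nrow(X)
  if (is.null(rownames(X))) rownames(X) <- paste0("item", seq_len(m))
  if (perplexity >= m) stop("perplexity must be smaller than the number of items")
  if (3 * perplexity > m - 1)
    stop("perplexity too large for ", m, " items (need 3*perplexity <= m - 1)")
  if (perplexity < 5 || perplexity > 50)
    warning("perplexity outside the recommended [5, 50] band")
  if (n_iter < 250L) warning("n_iter < 250 iterations is typically unstable")
  if (n_restarts < 1L) stop("n_restarts must be >= 1")
  seeds <- as.integer(seed) + seq_len(n_restarts) - 1L
  runs <- lapply(seeds, function(s) {
    set.seed(s)
    fit <- Rtsne::Rtsne(X, dims = 2L, perplexity = perplexity, theta = 0,
                        max_iter = as.integer(n_iter), pca = FALSE,
                        check_duplicates = FALSE, verbose = FALSE)
    list(Y = fit$Y, kl = unname(utils::tail(fit$itercosts, 1L)))
  })
  kls <- vapply(runs, `[[`, 0, "kl")
  best <- which.min(kls)
  Y <- runs[[best]]$Y
  rownames(Y) <- rownames(X)
  colnames(Y) <- c("x", "y")
  structure(list(items = rownames(X), coords2d = Y,
                 kl_divergence = kls[best], perplexity = perplexity,
                 n_iter = as.integer(n_iter), seed = seeds[best],
                 n_restarts = as.integer(n_restarts),
                 restart_log = data.frame(seed = seeds, kl = kls)),
            class = "semantic_map")
}

#' @export
print.semantic_map <- function(x, ...) {
  cat(sprintf(
    "<semantic_map: %d items, perplexity %.4g, %d iters, best KL %.4f over %d restart(s)>\n",
    length(x$items), x$perplexity, x$n_iter, x$kl_divergence, x$n_restarts))
  invisible(x)
}

#' Construct a sub-category labeling
#'
#' Every item carries exactly one label (the structure is unambiguous by
#' construction; duplicated items are an error).
#'
#' @param items character vector of item names.
#' @param labels character vector of sub-category labels, same length.
#' @param source `"kmeans"` or `"manual"`.
#' @return object of class `subcategory_labeling`: named character vector
#'   `mapping` (item -> label), `labels` (sorted unique), `source`.
#' @export
subcategory_labeling <- function(items, labels, source = c("kmeans", "manual")) {
  source <- match.arg(source)
  items <- as.character(items); labels <- as.character(labels)
  if (length(items) != length(labels)) stop("items and labels lengths differ")
  if (length(items) == 0L) stop("empty labeling")
  if (anyDuplicated(items))
    stop("item(s) labeled more than once: ",
         paste(unique(items[duplicated(items)]), collapse = ", "))
  mapping <- stats::setNames(labels, items)
  structure(list(mapping = mapping, labels = sort(unique(labels)),
                 source = source),
            class = "subcategory_labeling")
}

#' @export
print.subcategory_labeling <- function(x, ...) {
  cat(sprintf("<subcategory_labeling (%s): %d items in %d sub-categories>\n",
              x$source, length(x$mapping), length(x$labels)))
  invisible(x)
}

#' k-means sub-category labeling of a semantic map
#'
#' Clusters the 2D t-SNE coordinates by default (mirroring the visual
#' labeling workflow the map supports); set `use_mds = TRUE` together with an
#' `mds` argument to cluster the higher-dimensional MDS coordinates instead
#' (clustering t-SNE output is contested because t-SNE does not preserve
#' between-cluster distances).
#'
#' @param map a `semantic_map`.
#' @param k number of sub-categories, `2 <= k <= m`. Default 8.
#' @param seed RNG seed. Default 0.
#' @param n_init random initializations; best by within-cluster sum of
#'   squares. Default 25.
#' @param use_mds cluster `mds$coordinates` instead of the 2D map.
#' @param mds optional `mds_result`, required when `use_mds = TRUE`.
#' @return a [subcategory_labeling] with labels `"sc1" ... "sck"` (numbered
#'   by first appearance in item order).
#' @export
cluster_kmeans <- function(map, k = 8L, seed = 0L, n_init = 25L,
                           use_mds = FALSE, mds = NULL) {
  stopifnot(inherits(map, "semantic_map"))
  X <- if (use_mds) {
    if (is.null(mds)) stop("use_mds = TRUE requires an mds_result")
    mds$coordinates
  } else map$coords2d
  m <- nrow(X)
  if (k < 2L || k > m) stop("k must satisfy 2 <= k <= m")
  set.seed(as.integer(seed))
  cl <- if (k == m) seq_len(m)   # singleton clusters are trivially optimal
  else stats::kmeans(X, centers = k, nstart = as.integer(n_init),
                     iter.max = 100L)$cluster
  # stable label names: renumber clusters by order of first appearance
  first <- match(seq_len(k), cl)
  renum <- match(cl, order(first))
  subcategory_labeling(rownames(X), paste0("sc", renum), source = "kmeans")
}

#' Load a manual item -> sub-category label map
#'
#' @param path TSV file with two columns: item, label (no header by default;
#'   a `item\tlabel` header line is tolerated).
#' @param items character vector of items that must all be covered.
#' @param normalize_case normalize item strings before matching.
#' @return a [subcategory_labeling] with `source = "manual"`, restricted to
#'   `items` in their given order.
#' @export
load_manual_labels <- function(path, items, normalize_case = TRUE) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("item", "label"),
                          colClasses = "character", quote = "",
                          comment.char = "")
  if (nrow(df) > 0L && identical(tolower(df$item[1]), "item") &&
      identical(tolower(df$label[1]), "label"))
    df <- df[-1L, , drop = FALSE]
  if (normalize_case) {
    df$item <- normalize_item(df$item)
    items <- normalize_item(items)
  }
  amb <- tapply(df$label, df$item, function(l) length(unique(l)))
  if (any(amb > 1L))
    stop("item(s) mapped to more than one label: ",
         paste(names(amb)[amb > 1L], collapse = ", "))
  df <- df[!duplicated(df$item), , drop = FALSE]
  missing <- setdiff(items, df$item)
  if (length(missing) > 0L)
    stop("item(s) without a label: ", paste(missing, collapse = ", "))
  mapping <- stats::setNames(df$label, df$item)[items]
  subcategory_labeling(items, unname(mapping), source = "manual")
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement: 1 for identical partitions (up to label
#' names), approximately 0 for independent ones.
#'
#' @param a,b label vectors of equal length (any atomic type).
#' @return a single number in `[-1, 1]`.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("partitions must have equal length")
  n <- length(a)
  if (n < 2L) return(1)
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}

#' Stability of the map + labeling across perplexities and seeds
#'
#' For each (perplexity, seed) condition, embeds the MDS coordinates with
#' t-SNE and labels the map with k-means, then cross-tabulates every pair of
#' labelings with the adjusted Rand index.
#'
#' @param mds an `mds_result` (or coordinate matrix).
#' @param perplexities numeric vector of perplexity values.
#' @param seeds integer vector of seeds.
#' @param k number of k-means sub-categories. Default 8.
#' @param n_iter,n_restarts forwarded to [embed_tsne] (per condition).
#' @return object of class `stability_report`: `conditions` data frame
#'   (perplexity, seed, kl), `ari_matrix` (symmetric, unit diagonal),
#'   `labelings` (list of [subcategory_labeling]).
#' @export
stability_analysis <- function(mds, perplexities, seeds, k = 8L,
                               n_iter = 1500L, n_restarts = 1L) {
  grid <- expand.grid(perplexity = perplexities, seed = as.integer(seeds),
                      KEEP.OUT.ATTRS = FALSE)
  if (nrow(grid) < 2L) stop("need at least 2 (perplexity, seed) conditions")
  runs <- lapply(seq_len(nrow(grid)), function(i) {
    map <- embed_tsne(mds, perplexity = grid$perplexity[i],
                      n_iter = n_iter, n_restarts = n_restarts,
                      seed = grid$seed[i])
    list(kl = map$kl_divergence,
         lab = cluster_kmeans(map, k = k, seed = grid$seed[i]))
  })
  grid$kl <- vapply(runs, `[[`, 0, "kl")
  labs <- lapply(runs, `[[`, "lab")
  nc <- nrow(grid)
  A <- diag(1, nc)
  for (i in seq_len(nc - 1L)) for (j in seq(i + 1L, nc)) {
    A[i, j] <- A[j, i] <-
      adjusted_rand_index(labs[[i]]$mapping, labs[[j]]$mapping)
  }
  structure(list(conditions = grid, ari_matrix = A, labelings = labs),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  off <- x$ari_matrix[upper.tri(x$ari_matrix)]
  cat(sprintf(
    "<stability_report: %d conditions, pairwise ARI min %.3f / median %.3f>\n",
    nrow(x$conditions), min(off), stats::median(off)))
  invisible(x)
}

#' Write / read labeling TSV and map CSV
#'
#' @param lab a [subcategory_labeling]; `map` a `semantic_map`.
#' @param path file path.
#' @name map_io
#' @export
write_labels_tsv <- function(lab, path) {
  utils::write.table(
    data.frame(item = names(lab$mapping), label = unname(lab$mapping)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname map_io
#' @param map a `semantic_map`.
#' @export
write_map_csv <- function(map, path) {
  utils::write.csv(
    data.frame(item = map$items, x = map$coords2d[, 1], y = map$coords2d[, 2]),
    path, row.names = FALSE)
  invisible(path)
}

#' Scatter plot of a labeled semantic map
#'
#' @param map a `semantic_map`.
#' @param lab optional [subcategory_labeling] used to color points.
#' @param ... passed to [graphics::plot].
#' @return invisibly, the plotted data frame.
#' @export
plot_semantic_map <- function(map, lab = NULL, ...) {
  df <- data.frame(item = map$items, x = map$coords2d[, 1],
                   y = map$coords2d[, 2])
  col <- 1L
  if (!is.null(lab)) {
    lb <- lab$mapping[df$item]
    col <- as.integer(factor(lb, levels = lab$labels))
    df$label <- lb
  }
  graphics::plot(df$x, df$y, col = col, pch = 19,
                 xlab = "t-SNE 1", ylab = "t-SNE 2", ...)
  invisible(df)
}
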