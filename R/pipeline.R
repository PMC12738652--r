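#' Configuration of a Turing-space sweep
#'
#' Bundles every choice the end-to-end pipeline needs: the model, the fixed
#' and bounded parameters, the discretisation of parameter space, the spatial
#' grid, the simulation controls, the filtration convention and the cleaning
#' cutoffs. Defaults follow the study conditions: CIMA at \eqn{\delta = 1.5}
#' with \eqn{\alpha \in [0,20]}, \eqn{\sigma \in [1,20]} and \eqn{\beta}
#' ranging over its Turing-feasible interval; a 20 x 20 square at stepsize
#' 0.5; 549 nodes; evolution to \eqn{\tau = 250}; lower-star u / upper-star v
#' filtrations for CIMA (pure kinetics) and upper-star for both species for
#' Schnakenberg (cross kinetics).
#'
#' @param model `"cima"` or `"schnakenberg"`.
#' @param n_nodes number of parameter nodes (default 549).
#' @param delta fixed diffusivity ratio (CIMA default 1.5) or bounds
#'   (Schnakenberg default `c(25, 45)`).
#' @param alpha_range,sigma_range,beta_range parameter bounds. For CIMA,
#'   `beta_range = NULL` means the Turing-feasible interval at each
#'   \eqn{(\alpha, \sigma)}; for Schnakenberg all three of
#'   `alpha_range`/`beta_range`/`delta` bound the sampled box.
#' @param Lx,Ly,stepsize spatial grid (defaults 20, 20, 0.5).
#' @param sim a [sim_config()] (its `seed` is ignored; per-node seeds are
#'   derived from `seed`).
#' @param n_levels filtration levels (default 20).
#' @param prime coefficient field characteristic (default 2).
#' @param clean_cutoffs per-channel cleaning cutoffs (see
#'   [clean_barcode_set()]).
#' @param metric distance variant for clustering (default `"d1"`).
#' @param use_cleaned compute distances on cleaned barcodes (default TRUE).
#' @param seed master seed; node placement and per-node initial conditions
#'   derive from it.
#' @return list of class `sweep_config`.
#' @export
sweep_config <- function(model = "cima", n_nodes = 549L, delta = NULL,
                         alpha_range = NULL, sigma_range = NULL,
                         beta_range = NULL,
                         Lx = 20, Ly = 20, stepsize = 0.5,
                         sim = sim_config(), n_levels = 20L, prime = 2L,
                         clean_cutoffs = c(B0u = 5, B1u = 0, B0v = 5, B1v = 5),
                         metric = "d1", use_cleaned = TRUE, seed = 1L) {
  model <- match.arg(tolower(model), c("cima", "schnakenberg"))
  if (model == "cima") {
    if (is.null(delta)) delta <- 1.5
    if (is.null(alpha_range)) alpha_range <- c(0, 20)
    if (is.null(sigma_range)) sigma_range <- c(1, 20)
  } else {
    if (is.null(delta)) delta <- c(25, 45)
    if (is.null(alpha_range)) alpha_range <- c(0.01, 0.3)
    if (is.null(beta_range)) beta_range <- c(0.5, 1.8)
    sigma_range <- c(1, 1)
  }
  structure(list(model = model, n_nodes = as.integer(n_nodes), delta = delta,
                 alpha_range = alpha_range, sigma_range = sigma_range,
                 beta_range = beta_range, Lx = Lx, Ly = Ly,
                 stepsize = stepsize, sim = sim, n_levels = n_levels,
                 prime = as.integer(prime), clean_cutoffs = clean_cutoffs,
                 metric = metric, use_cleaned = use_cleaned,
                 seed = as.integer(seed)),
            class = "sweep_config")
}

# Halton low-discrepancy sequence (van der Corput radical inverse per axis)
halton <- function(n, dim, skip = 0L) {
  primes <- c(2, 3, 5, 7, 11, 13)[seq_len(dim)]
  radical_inverse <- function(i, b) {
    f <- 1; r <- 0
    while (i > 0) { f <- f / b; r <- r + f * (i %% b); i <- i %/% b }
    r
  }
  sapply(primes, function(b)
    vapply(seq_len(n) + skip, radical_inverse, numeric(1), b = b))
}

#' Discretise the restricted Turing space into parameter nodes
#'
#' Places `n_nodes` quasi-uniform points strictly inside the region where the
#' four Turing conditions hold, by rejection sampling of a low-discrepancy
#' (Halton) sequence over the configured parameter box; for CIMA the third
#' coordinate parametrises the Turing-feasible \eqn{\beta} interval at the
#' sampled \eqn{(\alpha, \sigma)}, which concentrates nodes where patterns
#' exist. Deterministic for a fixed `config$seed` (used as the sequence
#' offset).
#'
#' @param config a [sweep_config()].
#' @return list of [model_params()], each satisfying all Turing conditions.
#' @export
discretize_turing_space <- function(config) {
  stopifnot(inherits(config, "sweep_config"))
  n <- config$n_nodes
  nodes <- vector("list", n)
  got <- 0L
  skip <- (config$seed %% 1000L) * 7919L
  batch <- max(64L, 4L * n)
  tried <- 0L
  while (got < n) {
    H <- halton(batch, 3L, skip = skip + tried)
    tried <- tried + batch
    for (i in seq_len(nrow(H))) {
      if (got >= n) break
      al <- config$alpha_range[1] +
        H[i, 1] * diff(config$alpha_range)
      if (config$model == "cima") {
        sg <- config$sigma_range[1] + H[i, 2] * diff(config$sigma_range)
        bb <- cima_beta_bounds(al, sg, config$delta)
        lo <- bb$lo; hi <- bb$hi
        if (!is.null(config$beta_range)) {
          lo <- max(lo, config$beta_range[1]); hi <- min(hi, config$beta_range[2])
        }
        if (!is.finite(lo) || hi <= lo) next
        be <- lo + H[i, 3] * (hi - lo)
        p <- try(model_params("cima", al, be, config$delta, sg), silent = TRUE)
      } else {
        be <- config$beta_range[1] + H[i, 2] * diff(config$beta_range)
        de <- config$delta[1] + H[i, 3] * diff(range(config$delta))
        p <- try(model_params("schnakenberg", al, be, de), silent = TRUE)
      }
      if (inherits(p, "try-error")) next
      tc <- try(turing_conditions(linearise(p)), silent = TRUE)
      if (inherits(tc, "try-error") || !tc[["in_space"]]) next
      got <- got + 1L
      nodes[[got]] <- p
    }
    if (tried > 4000L * n)
      stop("bounds contain (almost) no Turing-space points")
  }
  nodes
}

# stable short hash of a configuration (polynomial rolling hash, 2^31-1)
config_hash <- function(config) {
  s <- paste(deparse(config), collapse = "")
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 131 + ch) %% 2147483647
  sprintf("%08x", h)
}

#' Run the simulate-filter-persist sweep over parameter nodes
#'
#' For every node: integrates the PDE from a seeded Gaussian-perturbed steady
#' state, builds the model's filtration pair (CIMA: lower-star u, upper-star
#' v; Schnakenberg: upper-star u and v), reduces both and stores the four
#' barcodes plus the amplitude diagnostic \eqn{\max u - \min u}. Per-node
#' seeds are `seed + node index`. When `cache_dir` is given, finished nodes
#' are written to disk keyed by the configuration hash and node index, and
#' reruns resume from the cache. A node whose solver fails is flagged (entry
#' of class `sweep_failure`) and the sweep continues.
#'
#' @param nodes list of [model_params()] from [discretize_turing_space()].
#' @param config a [sweep_config()].
#' @param cache_dir optional directory for per-node caching.
#' @param verbose print per-node progress to stderr.
#' @return list of [barcode_set()]s (or `sweep_failure` entries), one per
#'   node.
#' @export
run_sweep <- function(nodes, config, cache_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "sweep_config"))
  grid <- build_grid(config$Lx, config$Ly, config$stepsize)
  cx <- triangulate_grid(grid)
  hash <- config_hash(config)
  if (!is.null(cache_dir) && !dir.exists(cache_dir))
    dir.create(cache_dir, recursive = TRUE)
  dirs <- if (config$model == "cima") c(u = "lower", v = "upper")
          else c(u = "upper", v = "upper")

  out <- vector("list", length(nodes))
  for (i in seq_along(nodes)) {
    cache_file <- if (!is.null(cache_dir))
      file.path(cache_dir, sprintf("%s_node%04d.rds", hash, i)) else NULL
    if (!is.null(cache_file) && file.exists(cache_file)) {
      out[[i]] <- readRDS(cache_file)
      next
    }
    p <- nodes[[i]]
    cfg <- config$sim
    cfg$seed <- (config$seed + i) %% 2147483647L
    res <- try({
      sim <- simulate_pattern(p, grid, cfg)
      fu <- star_filtration(sim$u, cx, dirs[["u"]], config$n_levels)
      fv <- star_filtration(sim$v, cx, dirs[["v"]], config$n_levels)
      bu <- compute_barcodes(fu, p = config$prime)
      bv <- compute_barcodes(fv, p = config$prime)
      barcode_set(sprintf("node_%04d", i),
                  B0u = bu$B0, B1u = bu$B1, B0v = bv$B0, B1v = bv$B1,
                  params = p,
                  meta = list(amplitude_u = diff(range(sim$u$values)),
                              status = sim$status, time = sim$time,
                              seed = cfg$seed))
    }, silent = TRUE)
    if (inherits(res, "try-error")) {
      res <- structure(list(node_id = sprintf("node_%04d", i), params = p,
                            error = attr(res, "condition")$message),
                       class = "sweep_failure")
    }
    out[[i]] <- res
    if (!is.null(cache_file)) saveRDS(res, cache_file)
    if (verbose)
      message(sprintf("[%d/%d] %s", i, length(nodes),
                      if (inherits(res, "sweep_failure")) "FAILED" else
                        res$meta$status))
  }
  out
}

#' Cluster the output of a sweep
#'
#' Cleans the barcodes (unless `config$use_cleaned` is FALSE), builds the
#' distance matrix under the configured metric and selects linkage and k by
#' silhouette. Failed nodes are dropped (with a warning).
#'
#' @param sweep output of [run_sweep()].
#' @param config a [sweep_config()].
#' @param k_range candidate cluster counts (default `2:12`).
#' @return list with `clustering` ([select_clustering()] result), `dmat`,
#'   `nodes` (the surviving barcode sets).
#' @export
cluster_sweep <- function(sweep, config, k_range = 2:12) {
  ok <- !vapply(sweep, inherits, logical(1), "sweep_failure")
  if (any(!ok))
    warning(sprintf("%d node(s) failed and were dropped", sum(!ok)))
  nodes <- sweep[ok]
  if (length(nodes) < 3L) stop("need at least 3 successful nodes to cluster")
  if (config$use_cleaned)
    nodes <- lapply(nodes, clean_barcode_set, cutoffs = config$clean_cutoffs)
  dmat <- distance_matrix(nodes, variant = config$metric)
  list(clustering = select_clustering(dmat, k_range = k_range),
       dmat = dmat, nodes = nodes)
}

#' Assemble and write a sweep report
#'
#' Emits the cluster labels (CSV), the silhouette table over linkage and k
#' (CSV) and a JSON summary with the configuration hash, metric, selected
#' clustering and per-node parameters, amplitudes and labels. With fewer than
#' two successful nodes the clustering section is omitted and only the node
#' table is written.
#'
#' @param sweep output of [run_sweep()].
#' @param clustered output of [cluster_sweep()], or `NULL`.
#' @param dir output directory (created if missing).
#' @param config a [sweep_config()].
#' @return (invisibly) the report list, as written to `report.json`.
#' @export
sweep_report <- function(sweep, clustered = NULL, dir, config) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ok <- !vapply(sweep, inherits, logical(1), "sweep_failure")
  node_tab <- do.call(rbind, lapply(sweep, function(s) {
    p <- s$params
    data.frame(node_id = s$node_id, alpha = p$alpha, beta = p$beta,
               delta = p$delta, sigma = p$sigma,
               failed = inherits(s, "sweep_failure"),
               amplitude_u = if (inherits(s, "sweep_failure")) NA_real_
                             else s$meta$amplitude_u)
  }))
  report <- list(config_hash = config_hash(config), model = config$model,
                 metric = config$metric, n_nodes = length(sweep),
                 n_failed = sum(!ok))
  if (!is.null(clustered)) {
    labels <- clustered$clustering$labels
    node_tab$cluster <- NA_integer_
    node_tab$cluster[match(names(labels), node_tab$node_id)] <- labels
    utils::write.csv(clustered$clustering$scores,
                     file.path(dir, "silhouette_scores.csv"),
                     row.names = FALSE)
    report$clustering <- list(k = clustered$clustering$k,
                              linkage = clustered$clustering$linkage,
                              silhouette = clustered$clustering$silhouette)
  }
  utils::write.csv(node_tab, file.path(dir, "labels.csv"), row.names = FALSE)
  report$nodes <- node_tab
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  invisible(report)
}
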