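#' Clustering parameters for network construction
#'
#' @param alpha negative-exponential dispersal kernel parameter (1/km).
#' @param b exponent of the area product in the pairwise similarity.
#' @param q linkage control: cross-cluster similarity is damped by
#'   `min(n1, n2)^(1 - q)`, so q = 1 is the pure geometric mean and larger q
#'   penalizes merging large clusters.
#' @param cut similarity threshold at which merging stops, or `NULL` when a
#'   target cluster count `k` is given.
#' @param k target number of clusters (used when `cut` is NULL).
#' @return list of class `cluster_params`.
#' @export
cluster_params <- function(alpha = 1.0, b = 0.5, q = 1.5, cut = NULL, k = NULL) {
  stopifnot(alpha > 0, b >= 0, q >= 1)
  if (is.null(cut) && is.null(k)) stop("either cut or k must be given")
  structure(list(alpha = alpha, b = b, q = q, cut = cut, k = k),
            class = "cluster_params")
}

#' Cluster patches into semi-independent networks
#'
#' Agglomerative clustering on the connectivity-style similarity
#' `s_ij = (A_i A_j)^b exp(-alpha d_ij)`: at each step the pair of clusters
#' with the largest cross-similarity is merged, where the cross-similarity of
#' two clusters is the geometric mean of all cross-pair `s_ij`, damped by
#' `min(n1, n2)^(1-q)`. Merging stops when the best similarity drops below
#' `cut` (or when `k` clusters remain). Similarity ties are broken
#' deterministically towards the earliest pair in input row order.
#'
#' Clustering uses physical distances only; dispersal barriers such as
#' forest tracts are ignored. A pre-computed assignment (e.g. a published
#' network division) can be used instead via [network_assignment].
#'
#' @param x landscape.
#' @param params a [cluster_params].
#' @return Object of class `network_assignment`: data.frame with columns
#'   `patch_id`, `network_id` (integer, contiguous 1..n_networks), plus
#'   attribute `n_networks`.
#' @export
cluster_patches <- function(x, params = cluster_params(cut = 0.01)) {
  p <- x$patches
  n <- nrow(p)
  if (!is.null(params$k) && is.null(params$cut) && params$k > n)
    stop("target cluster count exceeds number of patches")
  if (n == 1)
    return(network_assignment(data.frame(patch_id = p$id, network_id = 1L)))

  ## log-similarity of single patches; -Inf never merges
  ls <- params$b * (log(p$area_ha) %o% rep(1, n) + rep(1, n) %o% log(p$area_ha)) -
    params$alpha * x$dist
  diag(ls) <- -Inf

  ## state: members list, summed cross log-sims L[a,b] = sum over cross pairs,
  ## V[a,b] = current cross log-similarity (geometric mean + size damping)
  members <- as.list(seq_len(n))
  sizes <- rep(1L, n)
  L <- ls
  V <- ls                         # sizes all 1, damping term is 0
  active <- rep(TRUE, n)

  n_active <- n
  target_k <- if (!is.null(params$k)) params$k else 1L
  while (n_active > target_k) {
    flat <- which.max(V)          # first max in column-major order: deterministic
    best <- V[flat]
    if (!is.null(params$cut) && best < log(params$cut)) break
    bj <- ((flat - 1L) %/% n) + 1L
    bi <- ((flat - 1L) %% n) + 1L
    ## merge bj into bi
    oth <- which(active); oth <- oth[oth != bi & oth != bj]
    L[bi, oth] <- L[oth, bi] <- L[bi, oth] + L[bj, oth]
    members[[bi]] <- c(members[[bi]], members[[bj]])
    sizes[bi] <- sizes[bi] + sizes[bj]
    active[bj] <- FALSE
    V[bj, ] <- V[, bj] <- -Inf
    if (length(oth) > 0) {
      v <- L[bi, oth] / (sizes[bi] * sizes[oth]) +
        (1 - params$q) * log(pmin(sizes[bi], sizes[oth]))
      V[bi, oth] <- V[oth, bi] <- v
    }
    n_active <- n_active - 1L
  }

  assign <- integer(n)
  nid <- 0L
  for (c0 in which(active)) {
    nid <- nid + 1L
    assign[members[[c0]]] <- nid
  }
  network_assignment(data.frame(patch_id = p$id, network_id = assign,
                                stringsAsFactors = FALSE))
}

#' Construct (or validate) a patch-to-network assignment
#'
#' @param df data.frame with columns `patch_id`, `network_id`.
#' @return `network_assignment` with contiguous integer network ids (original
#'   labels kept in the `label` column).
#' @export
network_assignment <- function(df) {
  stopifnot(all(c("patch_id", "network_id") %in% names(df)))
  if (anyDuplicated(df$patch_id))
    stop("patch assigned to more than one network")
  labels <- sort(unique(df$network_id))
  out <- data.frame(patch_id = as.character(df$patch_id),
                    network_id = match(df$network_id, labels),
                    label = as.character(df$network_id),
                    stringsAsFactors = FALSE)
  structure(out, class = c("network_assignment", "data.frame"),
            n_networks = length(labels))
}

#' @rdname network_assignment
#' @param path CSV with columns `patch_id,network_id`.
#' @export
read_network_assignment <- function(path) {
  network_assignment(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Between-network connectivity
#'
#' Expected immigration pressure on a network from all patches outside it:
#' `S_n = sum_{j not in n} N_j exp(-alpha d_nj)`, where `N_j` is the average
#' population size (mean annual larval-group count) of outside patch j and
#' `d_nj` its distance to the network centroid (unweighted mean of member
#' coordinates).
#'
#' @param assignment a [network_assignment].
#' @param x landscape.
#' @param mean_pop per-patch mean larval-group count, in landscape order.
#' @param alpha dispersal kernel parameter (1/km), default 1.
#' @return data.frame with `network_id`, `ext_connectivity`.
#' @export
network_connectivity <- function(assignment, x, mean_pop, alpha = 1) {
  stopifnot(alpha > 0, length(mean_pop) == n_patches(x))
  nid <- assignment$network_id[match(x$patches$id, assignment$patch_id)]
  if (anyNA(nid)) stop("assignment missing patches: ",
                       paste(x$patches$id[is.na(nid)], collapse = ", "))
  nets <- sort(unique(nid))
  s <- vapply(nets, function(nn) {
    inn <- nid == nn
    cx <- mean(x$patches$x_km[inn]); cy <- mean(x$patches$y_km[inn])
    out <- !inn
    if (!any(out)) return(0)
    d <- sqrt((x$patches$x_km[out] - cx)^2 + (x$patches$y_km[out] - cy)^2)
    sum(mean_pop[out] * exp(-alpha * d))
  }, numeric(1))
  data.frame(network_id = nets, ext_connectivity = s)
}

#' Per-network structural and dynamical summaries
#'
#' Aggregates the quantities the network-level regressions run on: patch
#' counts, pooled habitat area, centroid, bounding-box extent, time-averaged
#' fraction of patches occupied and (when capacity results are supplied)
#' time-averaged weighted occupancy p_lambda and metapopulation capacity.
#'
#' @param assignment a [network_assignment].
#' @param x landscape.
#' @param history optional [occupancy_history] (same patch set).
#' @param capacity optional named list of per-network [metapop_capacity]
#'   results (names = network ids as character).
#' @return data.frame, one row per network.
#' @export
network_summaries <- function(assignment, x, history = NULL, capacity = NULL) {
  nid <- assignment$network_id[match(x$patches$id, assignment$patch_id)]
  if (anyNA(nid))
    stop("assignment missing patches: ",
         paste(x$patches$id[is.na(nid)], collapse = ", "))
  if (!is.null(history) &&
      !all(rownames(history$occupied) %in% x$patches$id))
    stop("history contains unknown patch ids: ",
         paste(setdiff(rownames(history$occupied), x$patches$id), collapse = ", "))
  nets <- sort(unique(nid))
  rows <- lapply(nets, function(nn) {
    inn <- which(nid == nn)
    pp <- x$patches[inn, ]
    row <- data.frame(
      network_id = nn,
      n_patches = length(inn),
      pooled_area_ha = sum(pp$area_ha),
      centroid_x = mean(pp$x_km), centroid_y = mean(pp$y_km),
      extent_km2 = diff(range(pp$x_km)) * diff(range(pp$y_km)))
    if (!is.null(history)) {
      occ <- history$occupied[match(pp$id, rownames(history$occupied)), ,
                              drop = FALSE]
      frac <- colMeans(occ, na.rm = TRUE)         # per-year fraction occupied
      row$mean_fraction_occupied <- mean(frac[!is.nan(frac)])
      if (!is.null(capacity)) {
        cr <- capacity[[as.character(nn)]]
        row$lambda_M <- cr$lambda_M
        pl <- p_lambda_series(
          occupancy_history(occ), cr$weights[match(pp$id, names(cr$weights))])
        row$mean_p_lambda <- mean(pl, na.rm = TRUE)
      }
    }
    row
  })
  do.call(rbind, rows)
}
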