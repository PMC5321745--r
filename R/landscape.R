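#' Construct a landscape from a patch table
#'
#' A landscape is the immutable substrate of every downstream computation: a
#' table of habitat patches (planar coordinates in km, area in ha, four
#' habitat-quality variables) together with the full Euclidean distance
#' matrix between patches.
#'
#' The four quality variables describe what makes a dry meadow good habitat
#' for a checkerspot butterfly: abundance of the two larval host plants
#' (each scored ordinally 0--3), the fraction of host plants in dry
#' vegetation, the fraction surrounded by low vegetation, and the fraction
#' of the patch that is grazed (grazing tramples larval nests, so large
#' values mean low quality).
#'
#' @param patches data.frame with columns `id`, `x_km`, `y_km`, `area_ha`,
#'   `host_plantago`, `host_veronica`, `pct_dry`, `pct_low`, `pct_grazed`.
#'   Percentage columns are fractions in \[0, 1\].
#' @return An object of class `landscape`: a list with elements `patches`
#'   (the validated data.frame, row order preserved) and `dist` (symmetric
#'   km distance matrix with zero diagonal, dimnames = patch ids).
#' @export
landscape <- function(patches) {
  required <- c("id", "x_km", "y_km", "area_ha", "host_plantago",
                "host_veronica", "pct_dry", "pct_low", "pct_grazed")
  missing_cols <- setdiff(required, names(patches))
  if (length(missing_cols) > 0)
    stop("patch table is missing columns: ", paste(missing_cols, collapse = ", "))
  patches <- as.data.frame(patches)[, required]
  patches$id <- as.character(patches$id)

  dup <- unique(patches$id[duplicated(patches$id)])
  if (length(dup) > 0)
    stop("duplicate patch id(s): ", paste(dup, collapse = ", "))
  bad_area <- patches$id[!(is.finite(patches$area_ha) & patches$area_ha > 0)]
  if (length(bad_area) > 0)
    stop("non-positive or missing area for patch(es): ",
         paste(bad_area, collapse = ", "))
  for (v in c("host_plantago", "host_veronica")) {
    if (!all(patches[[v]] %in% 0:3))
      stop("ordinal host score '", v, "' must be in {0,1,2,3}")
  }
  for (v in c("pct_dry", "pct_low", "pct_grazed")) {
    if (any(patches[[v]] < 0 | patches[[v]] > 1))
      stop("fraction column '", v, "' outside [0,1]")
  }

  d <- as.matrix(stats::dist(patches[, c("x_km", "y_km")]))
  dimnames(d) <- list(patches$id, patches$id)
  structure(list(patches = patches, dist = d), class = "landscape")
}

#' @export
print.landscape <- function(x, ...) {
  cat("landscape:", nrow(x$patches), "patches,",
      format(sum(x$patches$area_ha), digits = 4), "ha pooled area\n")
  invisible(x)
}

#' Number of patches in a landscape
#' @param x landscape
#' @export
n_patches <- function(x) nrow(x$patches)

#' Read a patch table from CSV
#'
#' Expects the header `id,x_km,y_km,area_ha,host_plantago,host_veronica,
#' pct_dry,pct_low,pct_grazed`. Percentage columns may be stored on the
#' 0--100 scale in the file (declare with `percent_scale = 100`); they are
#' stored internally as fractions in \[0, 1\].
#'
#' @param path CSV file path.
#' @param percent_scale 1 if the file stores fractions, 100 if it stores
#'   percentages.
#' @return A [landscape].
#' @export
load_patch_table <- function(path, percent_scale = 1) {
  stopifnot(percent_scale %in% c(1, 100))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (v in c("pct_dry", "pct_low", "pct_grazed")) {
    if (any(df[[v]] < 0 | df[[v]] > percent_scale))
      stop("column '", v, "' outside [0,", percent_scale, "]")
    df[[v]] <- df[[v]] / percent_scale
  }
  landscape(df)
}

#' Composite habitat-quality index
#'
#' Each of four quality components (host-plant abundance, fraction dry,
#' fraction low vegetation, fraction grazed) is min--max rescaled across the
#' patch set to \[-1, 1\]; the grazing component's sign is then reversed
#' because large grazed fractions mean low quality. The index is the mean of
#' the four rescaled components, so it is itself bounded in \[-1, 1\]. The
#' two ordinal host-plant scores are combined into a single component before
#' rescaling: by default their maximum (the larvae need at least one host
#' species), optionally their sum.
#'
#' A component that is constant across patches carries no information and
#' maps to 0. Rescaling is over the patch set supplied, so the index is
#' invariant under affine transformations of any raw column.
#'
#' @param x landscape.
#' @param host how to combine the two host scores: "max" (default) or "sum".
#' @return Numeric vector of per-patch quality scores in \[-1, 1\], named by
#'   patch id.
#' @export
quality_index <- function(x, host = c("max", "sum")) {
  host <- match.arg(host)
  p <- x$patches
  if (nrow(p) < 2) {
    warning("quality index needs >= 2 patches for rescaling; returning 0")
    return(stats::setNames(rep(0, nrow(p)), p$id))
  }
  host_raw <- switch(host,
    max = pmax(p$host_plantago, p$host_veronica),
    sum = p$host_plantago + p$host_veronica)
  comps <- cbind(
    host = rescale_pm1(host_raw),
    dry  = rescale_pm1(p$pct_dry),
    low  = rescale_pm1(p$pct_low),
    graz = -rescale_pm1(p$pct_grazed))
  stats::setNames(rowMeans(comps), p$id)
}

## min-max to [-1, 1]; constant columns map to 0
rescale_pm1 <- function(v) {
  r <- range(v)
  if (r[1] == r[2]) return(rep(0, length(v)))
  2 * (v - r[1]) / (r[2] - r[1]) - 1
}

#' Construct an occupancy history
#'
#' Presence/absence of local populations per patch and year, from the annual
#' late-summer census of overwintering larval nests, with an explicit
#' missing-data mask (not every patch is surveyed every year) and the count
#' of larval groups found.
#'
#' @param occupied patch x year matrix of 0/1 with NA where unsurveyed;
#'   rownames are patch ids, colnames the years.
#' @param n_groups optional patch x year matrix of nonnegative larval-group
#'   counts with the same NA mask; defaults to `occupied` (1 group per
#'   occupied patch).
#' @return Object of class `occupancy_history` with elements `occupied`,
#'   `n_groups`, `years` (integer vector).
#' @export
occupancy_history <- function(occupied, n_groups = NULL) {
  occupied <- as.matrix(occupied)
  if (is.null(rownames(occupied)))
    stop("occupied must have patch ids as rownames")
  if (is.null(colnames(occupied)))
    colnames(occupied) <- seq_len(ncol(occupied))
  if (is.null(n_groups)) n_groups <- occupied
  n_groups <- as.matrix(n_groups)
  if (!identical(dim(occupied), dim(n_groups)))
    stop("occupied and n_groups dimensions differ")
  if (!identical(unname(is.na(occupied)), unname(is.na(n_groups))))
    stop("missing-data mask differs between occupied and n_groups")
  if (any(occupied[!is.na(occupied)] != (n_groups[!is.na(n_groups)] >= 1)))
    stop("occupied flag inconsistent with n_groups (occupied <=> n_groups >= 1)")
  structure(list(occupied = occupied, n_groups = n_groups,
                 years = as.integer(colnames(occupied))),
            class = "occupancy_history")
}

#' @export
print.occupancy_history <- function(x, ...) {
  cat("occupancy history:", nrow(x$occupied), "patches x",
      ncol(x$occupied), "years;",
      format(mean(is.na(x$occupied)) * 100, digits = 3), "% missing\n")
  invisible(x)
}

#' Read a long-format occupancy table from CSV
#'
#' Expects columns `patch_id,year,occupied,n_groups`; empty fields mean the
#' patch-year was not surveyed. Patch-years absent from the file are also
#' treated as missing.
#'
#' @param path CSV file path.
#' @param patch_ids optional character vector fixing the patch set and row
#'   order (defaults to the ids present in the file).
#' @return An [occupancy_history].
#' @export
read_occupancy <- function(path, patch_ids = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("patch_id", "year", "occupied", "n_groups") %in% names(df)))
  ids <- if (is.null(patch_ids)) unique(as.character(df$patch_id)) else patch_ids
  years <- sort(unique(df$year))
  occ <- matrix(NA_real_, length(ids), length(years),
                dimnames = list(ids, years))
  grp <- occ
  i <- match(as.character(df$patch_id), ids)
  j <- match(df$year, years)
  keep <- !is.na(i)
  occ[cbind(i[keep], j[keep])] <- df$occupied[keep]
  grp[cbind(i[keep], j[keep])] <- df$n_groups[keep]
  occupancy_history(occ, grp)
}

#' Observed incidence of occupancy per patch
#'
#' The fraction of surveyed years in which each patch was occupied — the
#' empirical incidence the equilibrium occupancy model is fitted to. Years
#' with missing surveys are excluded from both numerator and denominator;
#' patches never surveyed get `NA` incidence and are flagged.
#'
#' @param history an [occupancy_history].
#' @return data.frame with columns `patch_id`, `p_bar`, `n_observed_years`,
#'   `defined` (FALSE where the patch was never surveyed).
#' @export
incidence_from_history <- function(history) {
  occ <- history$occupied
  nobs <- rowSums(!is.na(occ))
  p_bar <- ifelse(nobs > 0, rowSums(occ, na.rm = TRUE) / pmax(nobs, 1), NA_real_)
  data.frame(patch_id = rownames(occ), p_bar = p_bar,
             n_observed_years = nobs, defined = nobs > 0,
             row.names = NULL, stringsAsFactors = FALSE)
}
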