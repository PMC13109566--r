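#' Construct a labelled point cloud
#'
#' A point cloud is an ordinary tibble with numeric columns `x`, `y`, `z`
#' (metres) and, optionally, an integer `label` column with `0 = leaf` and
#' `1 = stem`. Any further columns are carried along untouched and may hold
#' per-point feature channels. Because clouds are plain tibbles they compose
#' directly with dplyr verbs and the pipe.
#'
#' @param coords A data frame with columns `x`, `y`, `z`, or an N x 3 numeric
#'   matrix.
#' @param label Optional integer vector of per-point labels in `{0, 1}`.
#' @param name Optional free-text identifier, stored as the `"name"` attribute.
#' @return A validated tibble of class `stemleaf_cloud`.
#' @examples
#' point_cloud(matrix(runif(30), ncol = 3), label = rep(c(0, 1), 5))
#' @export
point_cloud <- function(coords, label = NULL, name = NULL) {
  if (is.matrix(coords)) {
    stopifnot(ncol(coords) == 3)
    coords <- tibble::tibble(x = coords[, 1], y = coords[, 2], z = coords[, 3])
  }
  cloud <- tibble::as_tibble(coords)
  if (!is.null(label)) cloud$label <- as.integer(label)
  cloud <- new_point_cloud(cloud, name = name)
  validate_point_cloud(cloud)
}

new_point_cloud <- function(df, name = NULL) {
  df <- tibble::as_tibble(df)
  class(df) <- unique(c("stemleaf_cloud", class(df)))
  if (!is.null(name)) attr(df, "name") <- name
  df
}

#' Validate a labelled point cloud
#'
#' Checks the invariants every operation in the package relies on: at least
#' one point, finite coordinates, and (when present) labels restricted to
#' `{0, 1}`.
#'
#' @param cloud A data frame with columns `x`, `y`, `z` and optionally `label`.
#' @return The cloud, invisibly unchanged, as a `stemleaf_cloud` tibble.
#' @export
validate_point_cloud <- function(cloud) {
  if (!is.data.frame(cloud)) stop("`cloud` must be a data frame", call. = FALSE)
  miss <- setdiff(c("x", "y", "z"), names(cloud))
  if (length(miss)) {
    stop("cloud is missing coordinate column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(cloud) < 1) stop("cloud must contain at least one point", call. = FALSE)
  xyz <- as.matrix(cloud[, c("x", "y", "z")])
  if (!is.numeric(xyz)) stop("coordinates must be numeric", call. = FALSE)
  bad <- which(!is.finite(xyz), arr.ind = TRUE)
  if (nrow(bad)) {
    stop("non-finite coordinate at point(s) ",
         paste(utils::head(unique(bad[, 1]), 5), collapse = ", "), call. = FALSE)
  }
  if ("label" %in% names(cloud)) {
    lab <- cloud$label
    if (length(lab) != nrow(cloud)) stop("label length must equal N", call. = FALSE)
    off <- which(!(lab %in% c(0L, 1L)))
    if (length(off)) {
      stop("labels outside {0, 1} at indices: ",
           paste(utils::head(off, 10), collapse = ", "), call. = FALSE)
    }
  }
  invisible(new_point_cloud(cloud, name = attr(cloud, "name")))
}

#' Coordinate matrix of a cloud
#'
#' @param cloud A point-cloud data frame.
#' @return An N x 3 numeric matrix.
#' @export
cloud_coords <- function(cloud) {
  unname(as.matrix(cloud[, c("x", "y", "z")]))
}

has_labels <- function(cloud) "label" %in% names(cloud)

#' @export
print.stemleaf_cloud <- function(x, ...) {
  nm <- attr(x, "name")
  cat("# A point cloud", if (!is.null(nm)) paste0("'", nm, "'"), "with",
      nrow(x), "points", if (has_labels(x)) "(labelled)" else "(unlabelled)", "\n")
  NextMethod()
}

# Run code under a temporary RNG state so seeded operations never disturb
# the caller's random stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
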