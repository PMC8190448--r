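#' Community incidence data with site coordinates
#'
#' Bundles a binary site-by-species incidence matrix with projected site
#' coordinates (km).  Coordinates are treated as planar: the study regions
#' this package targets are small enough that geodesic corrections are
#' irrelevant for the monotone distances used by the dispersal null model.
#'
#' @param incidence Binary matrix, sites in rows, species in columns, with
#'   dimnames.
#' @param xy Two-column matrix or data frame of site coordinates in km, rows
#'   matching (or named by) the incidence row names.
#' @return An object of class `community_data`: a list with elements
#'   `incidence` and `xy`.
#' @export
community_data <- function(incidence, xy) {
  incidence <- as.matrix(incidence)
  if (is.null(rownames(incidence)) || is.null(colnames(incidence)))
    stop("incidence matrix needs site row names and species column names",
         call. = FALSE)
  if (!all(incidence %in% c(0, 1)))
    stop("incidence entries must be 0/1", call. = FALSE)
  storage.mode(incidence) <- "double"
  xy <- as.matrix(as.data.frame(xy)[, c("x", "y")])
  if (is.null(rownames(xy))) rownames(xy) <- rownames(incidence)
  missing_sites <- setdiff(rownames(incidence), rownames(xy))
  if (length(missing_sites))
    stop("sites missing coordinates: ", paste(missing_sites, collapse = ", "),
         call. = FALSE)
  xy <- xy[rownames(incidence), , drop = FALSE]
  if (any(!is.finite(xy))) stop("site coordinates must be finite", call. = FALSE)
  empty_spp <- colSums(incidence) == 0
  if (any(empty_spp)) {
    warning("dropping species with no occurrences: ",
            paste(colnames(incidence)[empty_spp], collapse = ", "), call. = FALSE)
    incidence <- incidence[, !empty_spp, drop = FALSE]
  }
  if (any(rowSums(incidence) < 1))
    stop("every site must contain at least one species", call. = FALSE)
  structure(list(incidence = incidence, xy = xy), class = "community_data")
}

#' Read community data from CSV
#'
#' `path_matrix` is a CSV with a `site` key column and one 0/1 column per
#' species; `path_coords` is a CSV with columns `site`, `x`, `y` (km).
#'
#' @param path_matrix,path_coords File paths.
#' @return A [community_data] object.  Species columns that are all zero are
#'   dropped with a warning.
#' @export
read_community <- function(path_matrix, path_coords) {
  m <- utils::read.csv(path_matrix, check.names = FALSE)
  co <- utils::read.csv(path_coords, check.names = FALSE)
  if (!"site" %in% names(m) || !all(c("site", "x", "y") %in% names(co)))
    stop("incidence CSV needs a 'site' column; coordinates CSV needs 'site', 'x', 'y'",
         call. = FALSE)
  inc <- as.matrix(m[, setdiff(names(m), "site"), drop = FALSE])
  rownames(inc) <- as.character(m$site)
  xy <- data.frame(x = co$x, y = co$y, row.names = as.character(co$site))
  community_data(inc, xy)
}

#' @rdname read_community
#' @param x A `community_data` object.
#' @export
write_community <- function(x, path_matrix, path_coords) {
  stopifnot(inherits(x, "community_data"))
  utils::write.csv(data.frame(site = rownames(x$incidence), x$incidence,
                              check.names = FALSE),
                   path_matrix, row.names = FALSE)
  utils::write.csv(data.frame(site = rownames(x$xy),
                              x = x$xy[, "x"], y = x$xy[, "y"]),
                   path_coords, row.names = FALSE)
  invisible(x)
}

#' @export
print.community_data <- function(x, ...) {
  rs <- rowSums(x$incidence)
  cat("Community data:", nrow(x$incidence), "sites x", ncol(x$incidence),
      "species\n  richness", min(rs), "-", max(rs),
      sprintf("(mean %.2f)\n", mean(rs)))
  invisible(x)
}

#' Inter-site distance matrix (km)
#' @param x A `community_data` object.
#' @export
site_distances <- function(x) {
  as.matrix(stats::dist(x$xy))
}

#' Species flowering traits
#'
#' Per-species pistil length (mm) and flowering period as calendar start/end
#' months (1-12); periods may wrap the year end (e.g. Nov-Feb).
#'
#' @param species Character vector of species names.
#' @param pistil_length Positive lengths, mm.
#' @param flower_start,flower_end Integer months in 1..12.
#' @return A data frame of class `trait_table`, one row per species.
#' @export
trait_table <- function(species, pistil_length, flower_start, flower_end) {
  species <- as.character(species)
  if (anyDuplicated(species)) stop("duplicate species in trait table", call. = FALSE)
  if (any(!is.finite(pistil_length)) || any(pistil_length <= 0))
    stop("pistil_length must be positive", call. = FALSE)
  ok <- function(m) all(is.finite(m)) && all(m == round(m)) && all(m >= 1) && all(m <= 12)
  if (!ok(flower_start) || !ok(flower_end))
    stop("flowering months must be integers in 1..12", call. = FALSE)
  structure(data.frame(species = species,
                       pistil_length = as.numeric(pistil_length),
                       flower_start = as.integer(flower_start),
                       flower_end = as.integer(flower_end),
                       stringsAsFactors = FALSE,
                       row.names = species),
            class = c("trait_table", "data.frame"))
}

#' @rdname trait_table
#' @param path CSV with columns `species`, `pistil_length`, `flower_start`,
#'   `flower_end`.
#' @export
read_traits <- function(path) {
  d <- utils::read.csv(path)
  trait_table(d$species, d$pistil_length, d$flower_start, d$flower_end)
}

#' @rdname trait_table
#' @param x A `trait_table`.
#' @export
write_traits <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(x)
}
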