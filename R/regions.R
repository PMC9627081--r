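# Biogeographic sub-model routing. Species x ocean-basin presence/absence
# tables are clustered (basins as items, Euclidean distance on their
# presence vectors, average-linkage agglomerative clustering) into region
# groups; classical MDS coordinates are emitted so the grouping can also be
# read off an ordination plot. Each region's sub-model carries only the
# species recorded in at least one member basin, which is what keeps
# allopatric lookalike species out of each other's catalogs.

#' Read a species x basin presence/absence CSV
#'
#' First column: species names; remaining columns: basins. Presence tokens
#' are `x`, `X` or `1`; absence tokens are `-` (ASCII or Unicode hyphen),
#' `0` or an empty cell. Any other token is an error naming the offending
#' row and column.
#'
#' @param path CSV path.
#' @return Logical matrix of class `jf_presence` (species rows, basin
#'   columns). Species present nowhere are kept but flagged via a warning;
#'   they are unroutable.
#' @export
read_presence <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 2L) {
    stop("read_presence: need a species column plus at least one basin",
         call. = FALSE)
  }
  species <- as.character(df[[1L]])
  if (anyDuplicated(species)) {
    stop("read_presence: duplicate species row(s): ",
         paste(unique(species[duplicated(species)]), collapse = ", "),
         call. = FALSE)
  }
  basins <- names(df)[-1L]
  if (anyDuplicated(basins)) {
    stop("read_presence: duplicate basin column(s)", call. = FALSE)
  }
  m <- matrix(FALSE, length(species), length(basins),
              dimnames = list(species, basins))
  for (j in seq_along(basins)) {
    raw <- trimws(as.character(df[[j + 1L]]))
    present <- raw %in% c("x", "X", "1")
    absent <- raw %in% c("-", "‐", "‑", "–", "0", "", NA)
    bad <- which(!present & !absent)
    if (length(bad) > 0L) {
      stop("read_presence: unknown token '", raw[bad[1L]],
           "' at species '", species[bad[1L]], "', basin '", basins[j],
           "'", call. = FALSE)
    }
    m[, j] <- present
  }
  unroutable <- rownames(m)[rowSums(m) == 0L]
  if (length(unroutable) > 0L) {
    warning("read_presence: species present in no basin (unroutable): ",
            paste(unroutable, collapse = ", "), call. = FALSE)
  }
  structure(m, class = c("jf_presence", class(m)))
}

#' Bundled species x region occurrence table
#'
#' The 15-species occurrence table shipped with the package (collapsed to
#' the four region groups Atlantic/Mediterranean, Pacific, Arctic/Baltic
#' and Indian/South China, as compiled from the WoRMS database).
#'
#' @return A `jf_presence` matrix.
#' @export
jellyfish_presence <- function() {
  read_presence(system.file("extdata", "jellyfish_presence.csv",
                            package = "jellyeval", mustWork = TRUE))
}

#' Cluster ocean basins into sub-model regions
#'
#' Basins are characterized by their species presence vectors; pairwise
#' Euclidean distances feed average-linkage agglomerative clustering, cut
#' at `k` groups. Classical MDS coordinates of the same distance matrix are
#' returned so the grouping can be inspected on a 2-D ordination plot. The
#' procedure is deterministic given the input and invariant to row/column
#' order.
#'
#' @param presence A `jf_presence` matrix (see [read_presence()]).
#' @param k Number of regions (default 4). Must not exceed the number of
#'   basins.
#' @return Object of class `jf_regions`: list with `specs` (per region:
#'   `region` name, `basins`, `species` present in at least one member
#'   basin), `assignment` (named vector basin -> region name), `mds`
#'   (basin coordinates, up to 2 columns), and the `hclust` tree.
#' @export
cluster_basins <- function(presence, k = 4) {
  nb <- ncol(presence)
  if (k < 1 || k > nb) {
    stop("cluster_basins: need 1 <= k <= number of basins (", nb, ")",
         call. = FALSE)
  }
  d <- stats::dist(t(presence * 1), method = "euclidean")
  if (k == nb) {
    groups <- stats::setNames(seq_len(nb), colnames(presence))
    hc <- NULL
  } else if (k == 1L) {
    groups <- stats::setNames(rep(1L, nb), colnames(presence))
    hc <- stats::hclust(d, method = "average")
  } else {
    hc <- stats::hclust(d, method = "average")
    groups <- stats::cutree(hc, k = k)
  }
  mds <- stats::cmdscale(d, k = min(2L, nb - 1L))
  specs <- lapply(sort(unique(groups)), function(g) {
    basins <- names(groups)[groups == g]
    sub <- presence[, basins, drop = FALSE]
    list(region = paste(basins, collapse = "+"),
         basins = basins,
         species = rownames(presence)[rowSums(sub) > 0L])
  })
  names(specs) <- vapply(specs, `[[`, "", "region")
  assignment <- stats::setNames(
    vapply(specs, `[[`, "", "region")[match(groups, sort(unique(groups)))],
    names(groups))
  structure(list(specs = specs, assignment = assignment, mds = mds,
                 hclust = hc, k = k),
            class = "jf_regions")
}

#' @export
print.jf_regions <- function(x, ...) {
  cat("Basin clustering into", x$k, "region(s)\n")
  for (s in x$specs) {
    cat(sprintf("  %s: %d basin(s), %d species\n", s$region,
                length(s$basins), length(s$species)))
  }
  invisible(x)
}

#' Route a species to its regional sub-models
#'
#' @param presence A `jf_presence` matrix.
#' @param regions A `jf_regions` from [cluster_basins()].
#' @param species Species name (must be a row of `presence`).
#' @return Character vector of region names where the species is present in
#'   at least one member basin. A species present nowhere is an error, not
#'   an empty result.
#' @export
route_species <- function(presence, regions, species) {
  if (!species %in% rownames(presence)) {
    stop("route_species: unknown species '", species, "'", call. = FALSE)
  }
  hits <- vapply(regions$specs, function(s) species %in% s$species,
                 logical(1))
  if (!any(hits)) {
    stop("route_species: species '", species,
         "' is present in no basin and cannot be routed", call. = FALSE)
  }
  unname(vapply(regions$specs[hits], `[[`, "", "region"))
}

#' Filter a data set down to one region's sub-model
#'
#' Retains only instances of the region's member species and narrows the
#' class catalog accordingly. Geometry is never altered: filtering only
#' changes which rows are kept.
#'
#' @param gt Ground-truth table (or `NULL`).
#' @param det Detection table (or `NULL`).
#' @param regions A `jf_regions`.
#' @param region Region name (must match one of `regions$specs`).
#' @return List with `gt`, `det` (filtered; `NULL` stays `NULL`), and
#'   `catalog` (the narrowed [class_catalog()]). A region with no instances
#'   in the data yields empty tables, not an error.
#' @export
split_dataset_by_region <- function(gt, det, regions, region) {
  spec <- regions$specs[[region]]
  if (is.null(spec)) {
    stop("split_dataset_by_region: unknown region '", region, "'",
         call. = FALSE)
  }
  keep <- function(df) {
    if (is.null(df)) return(NULL)
    df[df$species %in% spec$species, , drop = FALSE]
  }
  list(gt = keep(gt), det = keep(det),
       catalog = class_catalog(spec$species), region = region)
}

#' Write region specs, routing table and ordination coordinates
#'
#' @param presence A `jf_presence` matrix.
#' @param regions A `jf_regions`.
#' @param out_dir Output directory.
#' @return Invisibly, the paths written (`region_specs.json`,
#'   `routing_table.csv`, `mds_coordinates.csv`).
#' @export
write_region_report <- function(presence, regions, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  specs_path <- file.path(out_dir, "region_specs.json")
  jsonlite::write_json(
    lapply(regions$specs, function(s) s[c("basins", "species")]),
    specs_path, auto_unbox = FALSE, pretty = TRUE)
  routable <- rownames(presence)[rowSums(presence) > 0L]
  routing <- do.call(rbind, lapply(routable, function(sp) {
    data.frame(species = sp,
               region = route_species(presence, regions, sp),
               stringsAsFactors = FALSE)
  }))
  routing_path <- file.path(out_dir, "routing_table.csv")
  utils::write.csv(routing, routing_path, row.names = FALSE)
  mds <- as.data.frame(regions$mds)
  names(mds) <- paste0("axis", seq_len(ncol(mds)))
  mds <- cbind(basin = rownames(regions$mds),
               region = regions$assignment[rownames(regions$mds)], mds)
  mds_path <- file.path(out_dir, "mds_coordinates.csv")
  utils::write.csv(mds, mds_path, row.names = FALSE)
  invisible(c(specs_path, routing_path, mds_path))
}
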