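#' Extract supra-threshold clusters from a corrected p-map
#'
#' Connected components of `{p < alpha}` inside the mask. Each cluster is
#' reported with its extent K_E (voxels), the minimum-p voxel as peak
#' (first in array order on ties), the peak's 1-based lattice index and
#' its world coordinate through the affine.
#'
#' @param p FWE-corrected p values over in-mask voxels (e.g. from
#'   [permutation_fwe()]), or a full 3D array.
#' @param stack a [cohort_stack()] supplying mask and affine, or a 3D
#'   logical mask array (identity affine then).
#' @param alpha significance threshold (default 0.05).
#' @param connectivity 6, 18 or 26.
#' @return A data.frame of class `cluster_table` (possibly empty):
#'   columns cluster, k_e, p_fwe, i, j, k, x, y, z; attribute
#'   `label_volume` holds the 3D cluster-label array.
#' @export
extract_clusters <- function(p, stack, alpha = 0.05, connectivity = 26) {
  if (inherits(stack, "cohort_stack")) {
    mask <- stack$mask; affine <- stack$affine
  } else {
    mask <- stack; affine <- diag(4)
  }
  pvol <- if (is.null(dim(p))) as_volume(mask, p, fill = 1) else p
  stopifnot(identical(dim(pvol), dim(mask)))
  sig <- (pvol < alpha) & mask
  labels <- label_components(sig, connectivity = connectivity)
  ids <- setdiff(sort(unique(as.integer(labels))), 0L)
  rows <- lapply(ids, function(id) {
    vox <- which(labels == id)
    peak <- vox[which.min(pvol[vox])]
    ijk <- arrayInd(peak, dim(mask))
    xyz <- vox_to_world(affine, ijk)
    data.frame(cluster = id, k_e = length(vox), p_fwe = min(pvol[vox]),
               i = ijk[1], j = ijk[2], k = ijk[3],
               x = xyz[1], y = xyz[2], z = xyz[3])
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cluster = integer(), k_e = integer(), p_fwe = numeric(),
               i = integer(), j = integer(), k = integer(),
               x = numeric(), y = numeric(), z = numeric())
  out <- out[order(-out$k_e), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "label_volume") <- labels
  attr(out, "alpha") <- alpha
  class(out) <- c("cluster_table", "data.frame")
  out
}

#' Attach atlas overlap percentages to a cluster table
#'
#' For every cluster, the percentage of its voxels falling in each atlas
#' label; labels overlapping less than `min_overlap` percent are
#' suppressed (study rule: 5% or more is reported).
#'
#' @param clusters a `cluster_table` from [extract_clusters()].
#' @param atlas 3D integer label volume on the same grid (0 = unlabeled).
#' @param lookup data.frame with columns `id`, `name`.
#' @param min_overlap suppression threshold in percent (default 5).
#' @return The cluster table with a list-column `labels` (per cluster a
#'   data.frame id, name, n_voxels, overlap_pct sorted by overlap) and a
#'   character column `label` summarising them.
#' @export
label_clusters <- function(clusters, atlas, lookup, min_overlap = 5) {
  labvol <- attr(clusters, "label_volume")
  if (is.null(labvol))
    stop("cluster table lacks its label volume; use extract_clusters()",
         call. = FALSE)
  if (!identical(dim(atlas), dim(labvol)))
    stop("atlas grid does not match the cluster grid; resample first",
         call. = FALSE)
  stopifnot(all(c("id", "name") %in% names(lookup)))
  lab_list <- lapply(clusters$cluster, function(id) {
    vox <- which(labvol == id)
    tab <- table(atlas[vox])
    df <- data.frame(id = as.integer(names(tab)),
                     n_voxels = as.integer(tab))
    df$overlap_pct <- 100 * df$n_voxels / length(vox)
    df <- merge(df, lookup, by = "id", all.x = TRUE)
    df$name[is.na(df$name)] <- "unlabeled"
    df <- df[df$overlap_pct >= min_overlap & df$id != 0L, , drop = FALSE]
    df[order(-df$overlap_pct), c("id", "name", "n_voxels", "overlap_pct")]
  })
  clusters$label <- vapply(lab_list, function(df) {
    if (!nrow(df)) return("-")
    paste(sprintf("%s (%.1f%%)", df$name, df$overlap_pct), collapse = "; ")
  }, character(1))
  clusters$labels <- lab_list
  clusters
}

#' Write a cluster table as TSV
#'
#' Columns mirror the usual cluster-report layout: label, K_E, p_FWE and
#' peak world coordinates.
#'
#' @param clusters a `cluster_table` (labelled or not).
#' @param path TSV path.
#' @export
write_cluster_table_tsv <- function(clusters, path) {
  df <- as.data.frame(clusters)
  df$labels <- NULL
  if (is.null(df$label)) df$label <- "-"
  df <- df[, c("label", "k_e", "p_fwe", "x", "y", "z")]
  names(df) <- c("label", "K_E", "P_FWEcorr", "x", "y", "z")
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
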