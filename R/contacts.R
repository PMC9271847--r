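#' Compute the native contact map of a structure
#'
#' Residues i and j (separated by at least `min_sep` in sequence) are in
#' contact when any heavy atom of i lies within `cutoff` of any heavy atom
#' of j (strict inequality).  Only one contact is stored per residue pair
#' however many atomic pairs are close, and each contact carries the
#' native C-alpha distance d_ij (in nm, the simulation length unit).
#' Hydrogens are stripped before the search.
#'
#' The default `min_sep = 3` reads "separated by at least three residues"
#' as |i - j| >= 3; pass `min_sep = 4` for the three-intervening-residues
#' reading.
#'
#' @param s an [rp_structure()].
#' @param cutoff heavy-atom cutoff in Angstrom (4.5 default; 5.5 and 6
#'   are common variants with denser, less perturbation-sensitive maps).
#' @param min_sep minimum sequence separation |i - j|.
#' @return An `rp_contact_map`: list with `n_residues`, `contacts`
#'   (data frame `i`, `j`, `dij` in nm), `cutoff`, `min_sep`.
#' @export
compute_contact_map <- function(s, cutoff = 4.5, min_sep = 3) {
  s <- strip_hydrogens(s)
  ca <- ca_xyz(s)  # errors MissingCA if absent
  a <- s$atoms
  hits <- cpp_residue_contacts(as.matrix(a[, c("x", "y", "z")]),
                               as.integer(a$resno), cutoff, as.integer(min_sep))
  dij <- sqrt(rowSums((ca[hits$i, , drop = FALSE] - ca[hits$j, , drop = FALSE])^2)) / 10
  new_contact_map(n_residues(s),
                  data.frame(i = hits$i, j = hits$j, dij = dij),
                  cutoff, min_sep, label = s$label)
}

new_contact_map <- function(n_residues, contacts, cutoff = NA_real_,
                            min_sep = NA_integer_, label = "") {
  contacts <- contacts[order(contacts$i, contacts$j), , drop = FALSE]
  rownames(contacts) <- NULL
  structure(list(n_residues = as.integer(n_residues), contacts = contacts,
                 M = nrow(contacts), cutoff = cutoff,
                 min_sep = as.integer(min_sep), label = label),
            class = "rp_contact_map")
}

#' @export
n_residues.rp_contact_map <- function(x) x$n_residues

#' @export
print.rp_contact_map <- function(x, ...) {
  cat(sprintf("<rp_contact_map> '%s': %d residues, M = %d contacts (cutoff %.1f A, |i-j| >= %d)\n",
              x$label, x$n_residues, x$M, x$cutoff, x$min_sep))
  invisible(x)
}

contact_keys <- function(cm) paste(cm$contacts$i, cm$contacts$j)

#' Composite contact map across several constructs
#'
#' Pools the contact maps of several RPs; each contact is annotated with
#' the number of input maps it is present in.  Backbone-driven contacts
#' (intra-helix, inter-strand) appear in all maps; variably packed
#' contacts in few.
#'
#' @param maps list of `rp_contact_map`s sharing `n_residues`.
#' @return An `rp_composite_map`: list with `n_residues`, `counts`
#'   (data frame `i`, `j`, `count`) and `n_maps`.
#' @export
composite_map <- function(maps) {
  stopifnot(length(maps) >= 1)
  n <- maps[[1]]$n_residues
  if (!all(vapply(maps, function(m) m$n_residues, integer(1)) == n)) {
    rp_stop("IncompatibleSizes", "contact maps have differing residue counts")
  }
  keys <- unlist(lapply(maps, contact_keys))
  tab <- table(keys)
  ij <- do.call(rbind, strsplit(names(tab), " "))
  counts <- data.frame(i = as.integer(ij[, 1]), j = as.integer(ij[, 2]),
                       count = as.integer(tab))
  counts <- counts[order(counts$i, counts$j), , drop = FALSE]
  rownames(counts) <- NULL
  structure(list(n_residues = n, counts = counts, n_maps = length(maps)),
            class = "rp_composite_map")
}

#' Difference map between the wild type and one permutant
#'
#' Partitions contacts into those common to both maps, those present only
#' in the wild type (lost on permutation) and those present only in the
#' permutant (gained).
#'
#' @param wt,rp `rp_contact_map`s with equal `n_residues`.
#' @return An `rp_difference_map` with data frames `common`, `wt_only`,
#'   `rp_only`.
#' @export
difference_map <- function(wt, rp) {
  if (wt$n_residues != rp$n_residues) {
    rp_stop("IncompatibleSizes", "contact maps have differing residue counts")
  }
  kw <- contact_keys(wt); kr <- contact_keys(rp)
  structure(list(
    n_residues = wt$n_residues,
    common = wt$contacts[kw %in% kr, , drop = FALSE],
    wt_only = wt$contacts[!kw %in% kr, , drop = FALSE],
    rp_only = rp$contacts[!kr %in% kw, , drop = FALSE]
  ), class = "rp_difference_map")
}

#' Normalized contact gain/loss per region across permutants
#'
#' For each named residue region and each RP, computes the number of
#' wild-type contacts lost and non-native contacts gained inside the
#' region, normalized by the wild-type contact count of that region
#' (`max(1, .)` guards regions without wild-type contacts).  A contact
#' belongs to a region only when both partners are inside it; contacts
#' straddling two named regions are attributed to an `interface` bucket
#' when requested.
#'
#' @param wt wild-type `rp_contact_map`.
#' @param rps list of permutant `rp_contact_map`s.
#' @param regions named list of residue-index vectors.
#' @param interface if `TRUE`, add an `interface` bucket for contacts
#'   whose partners fall in two different named regions.
#' @return data frame with columns `rp`, `region`, `gained`, `lost`,
#'   `n_wt` (wild-type contacts in the region).
#' @export
region_gain_loss <- function(wt, rps, regions, interface = FALSE) {
  stopifnot(is.list(regions), !is.null(names(regions)))
  if (any(vapply(regions, length, integer(1)) == 0)) {
    rp_warn("EmptyRegion", "one or more regions contain no residues")
  }
  assign_region <- function(df) {
    if (nrow(df) == 0) return(character(0))
    vapply(seq_len(nrow(df)), function(k) {
      inside <- names(regions)[vapply(regions, function(r)
        df$i[k] %in% r && df$j[k] %in% r, logical(1))]
      if (length(inside) >= 1) return(inside[1])
      if (interface) {
        ri <- names(regions)[vapply(regions, function(r) df$i[k] %in% r, logical(1))]
        rj <- names(regions)[vapply(regions, function(r) df$j[k] %in% r, logical(1))]
        if (length(ri) && length(rj) && ri[1] != rj[1]) return("interface")
      }
      NA_character_
    }, character(1))
  }
  wt_region <- assign_region(wt$contacts)
  buckets <- c(names(regions), if (interface) "interface")
  out <- list()
  for (p in seq_along(rps)) {
    dm <- difference_map(wt, rps[[p]])
    lost_r <- assign_region(dm$wt_only)
    gain_r <- assign_region(dm$rp_only)
    for (b in buckets) {
      n_wt <- sum(wt_region == b, na.rm = TRUE)
      out[[length(out) + 1]] <- data.frame(
        rp = p, region = b,
        gained = sum(gain_r == b, na.rm = TRUE) / max(1, n_wt),
        lost = sum(lost_r == b, na.rm = TRUE) / max(1, n_wt),
        n_wt = n_wt, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Detect variably packed (sensitive) residue segments
#'
#' Scans the composite map for maximal residue windows (length >= 3) in
#' which more than half of the composite contacts touching the window are
#' variable, i.e. present in at most `low_occupancy` of the pooled maps.
#' Such windows mark regions whose packing depends on the specific
#' amino-acid sizes placed there.
#'
#' @param composite an `rp_composite_map` built from at least 2 maps.
#' @param low_occupancy occupancy fraction at or below which a contact
#'   counts as variable.
#' @return data frame of segments (`start`, `end`, `frac_variable`);
#'   zero rows when packing is conserved everywhere.
#' @export
sensitive_regions <- function(composite, low_occupancy = 0.4) {
  stopifnot(inherits(composite, "rp_composite_map"), composite$n_maps >= 2)
  cc <- composite$counts
  variable <- cc$count / composite$n_maps <= low_occupancy
  n <- composite$n_residues
  res_frac <- vapply(seq_len(n), function(r) {
    touch <- cc$i == r | cc$j == r
    if (!any(touch)) return(NA_real_)
    mean(variable[touch])
  }, numeric(1))
  flag <- !is.na(res_frac) & res_frac > 0.5
  # maximal runs of flagged residues, length >= 3
  runs <- rle(flag)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  keep <- runs$values & runs$lengths >= 3
  if (!any(keep)) {
    return(data.frame(start = integer(0), end = integer(0),
                      frac_variable = numeric(0)))
  }
  data.frame(start = starts[keep], end = ends[keep],
             frac_variable = vapply(which(keep), function(k)
               mean(res_frac[starts[k]:ends[k]], na.rm = TRUE), numeric(1)))
}

#' Read/write contact maps as plain text
#'
#' The exchange format is whitespace-separated
#' `chain_i i chain_j j dij_nm` with `#` comments, interoperable with
#' structure-based-model contact files.
#'
#' @param cm an `rp_contact_map`.
#' @param file path.
#' @param n_residues residue count for [read_contact_map()] (defaults to
#'   the maximum index seen).
#' @return [write_contact_map()] returns `file`; [read_contact_map()] an
#'   `rp_contact_map`.
#' @export
write_contact_map <- function(cm, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("# contact map '%s': n_residues=%d cutoff=%.2f min_sep=%d",
                     cm$label, cm$n_residues, cm$cutoff, cm$min_sep), con)
  writeLines(sprintf("A %d A %d %.6f", cm$contacts$i, cm$contacts$j,
                     cm$contacts$dij), con)
  invisible(file)
}

#' @rdname write_contact_map
#' @export
read_contact_map <- function(file, n_residues = NULL) {
  lines <- readLines(file)
  header <- lines[startsWith(lines, "#")]
  lines <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  fields <- do.call(rbind, strsplit(trimws(lines), "\\s+"))
  contacts <- data.frame(i = as.integer(fields[, 2]), j = as.integer(fields[, 4]),
                         dij = as.numeric(fields[, 5]))
  meta <- regmatches(header, regexec("n_residues=(\\d+)", header))
  if (is.null(n_residues)) {
    n_residues <- if (length(meta) && length(meta[[1]]) == 2)
      as.integer(meta[[1]][2]) else max(contacts$j)
  }
  cutoff <- NA_real_; min_sep <- NA_integer_
  mc <- regmatches(header, regexec("cutoff=([0-9.]+) min_sep=(\\d+)", header))
  if (length(mc) && length(mc[[1]]) == 3) {
    cutoff <- as.numeric(mc[[1]][2]); min_sep <- as.integer(mc[[1]][3])
  }
  new_contact_map(n_residues, contacts, cutoff, min_sep,
                  label = basename(file))
}
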