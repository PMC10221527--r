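#' Detect taxon-metabolite associations shared across gut locations
#'
#' Intersects per-location association scans: a (taxon, metabolite) pair
#' is shared by a set of locations when it is significant
#' (q < `q_threshold`) in every one of them independently. Sign
#' concordance across the member locations is recorded, since a pair can
#' replicate with opposite directions (e.g. positive in cecum, negative
#' in faeces).
#'
#' @param scans named list of `association_scan` data.frames (one per
#'   location, >= 2), all at the same taxonomic level.
#' @param q_threshold FDR threshold defining significance.
#' @return list of class `cross_location_report`: `per_location_counts`,
#'   `shared` (data.frame: pair, locations sharing it, concordant flag,
#'   per-location z), `three_way` (pairs shared by all locations when 3+
#'   are given), `venn` (region counts over significant-pair sets).
#' @export
shared_associations <- function(scans, q_threshold = 0.05) {
  if (length(scans) < 2) stop("need scans from at least 2 locations")
  if (is.null(names(scans)) || any(names(scans) == "")) {
    names(scans) <- vapply(scans, function(s) s$location[1], character(1))
  }
  levels_ <- vapply(scans, function(s) s$level[1], character(1))
  if (length(unique(levels_)) != 1) {
    stop("all scans must be at the same taxonomic level (got: ",
         paste(unique(levels_), collapse = ", "), ")")
  }
  key <- function(s) paste(s$taxon_id, s$metabolite_id, sep = "\r")
  sig_sets <- lapply(scans, function(s) key(s)[s$q_value < q_threshold])
  counts <- vapply(sig_sets, length, integer(1))

  all_keys <- unique(unlist(sig_sets))
  member <- vapply(sig_sets, function(s) all_keys %in% s,
                   logical(length(all_keys)))
  if (length(all_keys) == 1) member <- matrix(member, nrow = 1)
  n_loc_sig <- rowSums(member)
  shared_keys <- all_keys[n_loc_sig >= 2]

  shared <- NULL
  if (length(shared_keys)) {
    parts <- strsplit(shared_keys, "\r", fixed = TRUE)
    z_by_loc <- lapply(scans, function(s) {
      stats::setNames(s$z_meta, key(s))
    })
    rows <- lapply(seq_along(shared_keys), function(i) {
      k <- shared_keys[i]
      locs <- names(scans)[member[match(k, all_keys), ]]
      zs <- vapply(locs, function(l) z_by_loc[[l]][[k]], numeric(1))
      data.frame(taxon_id = parts[[i]][1],
                 metabolite_id = parts[[i]][2],
                 locations = paste(locs, collapse = ","),
                 n_locations = length(locs),
                 concordant = length(unique(sign(zs))) == 1,
                 mean_z = mean(zs),
                 row.names = NULL)
    })
    shared <- do.call(rbind, rows)
    shared <- shared[order(-shared$n_locations, shared$taxon_id,
                           shared$metabolite_id), ]
    rownames(shared) <- NULL
  } else {
    shared <- data.frame(taxon_id = character(), metabolite_id = character(),
                         locations = character(), n_locations = integer(),
                         concordant = logical(), mean_z = numeric())
  }
  three_way <- shared[shared$n_locations == length(scans), , drop = FALSE]

  structure(list(per_location_counts = counts,
                 shared = shared,
                 three_way = three_way,
                 q_threshold = q_threshold,
                 venn = venn_counts(sig_sets)),
            class = "cross_location_report")
}

#' @export
print.cross_location_report <- function(x, ...) {
  cat("cross-location association report (q <", x$q_threshold, ")\n")
  cat("  significant pairs per location:\n")
  for (l in names(x$per_location_counts)) {
    cat(sprintf("    %-8s %d\n", l, x$per_location_counts[[l]]))
  }
  cat(sprintf("  shared by >=2 locations: %d (all locations: %d)\n",
              nrow(x$shared), nrow(x$three_way)))
  invisible(x)
}

#' Exact Venn region counts for 2 or more sets
#'
#' Enumerates, for every non-empty combination of the input sets, the
#' number of elements belonging to exactly that combination (exclusive
#' regions), so the counts satisfy inclusion-exclusion and sum to the
#' union size.
#'
#' @param sets named list (>= 2) of character vectors.
#' @return data.frame with columns `region` (member set names joined by
#'   `&`) and `count`.
#' @export
venn_counts <- function(sets) {
  if (length(sets) < 2) stop("need at least 2 sets")
  if (is.null(names(sets))) names(sets) <- paste0("set", seq_along(sets))
  elements <- unique(unlist(sets))
  membership <- vapply(sets, function(s) elements %in% s,
                       logical(length(elements)))
  if (length(elements) == 1) membership <- matrix(membership, nrow = 1)
  k <- length(sets)
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), k))[-1, , drop = FALSE]
  names(combos) <- names(sets)
  counts <- apply(combos, 1, function(combo) {
    if (length(elements) == 0) return(0L)
    sum(apply(membership, 1, function(mem) all(mem == combo)))
  })
  region <- apply(combos, 1, function(combo) {
    paste(names(sets)[as.logical(combo)], collapse = "&")
  })
  data.frame(region = region, count = as.integer(counts), row.names = NULL)
}
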