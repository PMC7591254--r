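#' Load developmental-stage gene sets from a GMT file
#'
#' Parses a GMT file (one record per line: set name, description, genes,
#' tab-separated) holding the seven microglial developmental stage sets -
#' YS (yolk sac), E1/E2 (early embryonic), P1/P2 (pre-microglia), A1/A2
#' (adult). The stage sets form a partition of the developmental marker
#' genes, so pairwise disjointness is validated on load (case-insensitive);
#' any shared gene raises an error naming the collisions. Set
#' `strict = FALSE` to allow overlapping exploratory sets.
#'
#' @param path GMT file path.
#' @param required set names that must be present (default the seven
#'   stages); use `NULL` to accept any collection.
#' @param strict enforce pairwise disjointness (default TRUE).
#' @return Named list of character vectors, class `stage_sets`, ordered as
#'   `required`.
#' @export
load_stage_sets <- function(path, required = stage_names(), strict = TRUE) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(x) unique(x[-(1:2)][nzchar(x[-(1:2)])]))
  names(sets) <- vapply(parts, `[`, character(1), 1)
  if (!is.null(required)) {
    missing <- setdiff(required, names(sets))
    if (length(missing)) {
      stop("GMT is missing required set(s): ",
           paste(missing, collapse = ", "))
    }
    sets <- sets[required]
  }
  if (strict) {
    nm <- names(sets)
    for (i in seq_len(length(sets) - 1)) for (j in (i + 1):length(sets)) {
      ov <- intersect(tolower(sets[[i]]), tolower(sets[[j]]))
      if (length(ov)) {
        stop("sets ", nm[i], " and ", nm[j], " are not disjoint: ",
             paste(head(ov, 10), collapse = ", "))
      }
    }
  }
  structure(sets, class = "stage_sets")
}

#' @rdname load_stage_sets
#' @export
stage_names <- function() c("YS", "E1", "E2", "P1", "P2", "A1", "A2")

#' Write gene sets as a GMT file
#'
#' @param sets named list of character vectors (e.g. `stage_sets`).
#' @param path output path.
#' @param description per-set description column (recycled).
#' @export
write_gmt <- function(sets, path, description = "") {
  lines <- mapply(function(nm, genes, desc) {
    paste(c(nm, desc, genes), collapse = "\t")
  }, names(sets), sets, rep_len(description, length(sets)))
  writeLines(unname(lines), path)
  invisible(path)
}

#' Overlap of a DEG list with the developmental stage sets
#'
#' Computes, for each stage set, the number and percentage of the DEGs
#' falling in that set (the donut-chart fractions), plus the unassigned
#' remainder. Matching is case-insensitive; an optional synonym map
#' translates DEG symbols before matching. Percentages are reported to two
#' decimals and, with disjoint sets, sum to 100 with the unassigned share.
#'
#' @param degs character vector of DE gene ids (deduplicated internally;
#'   must be non-empty).
#' @param sets a `stage_sets` list (or any named list of gene sets).
#' @param synonyms optional named character vector mapping DEG symbols to
#'   the set nomenclature.
#' @return data.frame (class `overlap_profile`) with one row per set plus
#'   an `unassigned` row: columns set, n_overlap, pct. The DEG total is in
#'   attribute `n_degs`.
#' @examples
#' overlap_fractions(c("a", "b", "c", "d"),
#'                   list(YS = "a", E1 = c("b", "c")))
#' @export
overlap_fractions <- function(degs, sets, synonyms = NULL) {
  degs <- unique(degs)
  if (length(degs) == 0) stop("empty DEG list: fractions are undefined")
  if (!is.null(synonyms)) {
    hit <- degs %in% names(synonyms)
    degs[hit] <- synonyms[degs[hit]]
    degs <- unique(degs)
  }
  dl <- tolower(degs)
  assigned <- rep(FALSE, length(degs))
  rows <- lapply(names(sets), function(nm) {
    inset <- dl %in% tolower(sets[[nm]])
    assigned <<- assigned | inset
    data.frame(set = nm, n_overlap = sum(inset),
               pct = round(100 * sum(inset) / length(degs), 2))
  })
  out <- do.call(rbind, rows)
  out <- rbind(out, data.frame(set = "unassigned",
                               n_overlap = sum(!assigned),
                               pct = round(100 * sum(!assigned) /
                                             length(degs), 2)))
  attr(out, "n_degs") <- length(degs)
  class(out) <- c("overlap_profile", class(out))
  out
}

#' Two-list Venn partition counts
#'
#' @param list_a,list_b gene lists (deduplicated internally).
#' @return List with `n_common`, `n_a_only`, `n_b_only`.
#' @examples
#' venn_compare(c("a", "b", "c"), c("b", "c", "d")) # 2, 1, 1
#' @export
venn_compare <- function(list_a, list_b) {
  a <- unique(list_a); b <- unique(list_b)
  common <- intersect(a, b)
  list(n_common = length(common),
       n_a_only = length(setdiff(a, b)),
       n_b_only = length(setdiff(b, a)))
}

#' Hypergeometric enrichment of a DEG list in a gene set
#'
#' Upper-tail hypergeometric probability of observing at least the realised
#' overlap between the DEGs and the set, drawing `|degs|` genes from a
#' universe of `universe_size` containing `|set|` set members. A generic
#' over-representation test for arbitrary gene collections.
#'
#' @param degs DEG list (or its size, as an integer scalar with
#'   `n_overlap` supplied).
#' @param set gene set (or its size).
#' @param universe_size number of genes in the universe.
#' @param n_overlap observed overlap; computed from the lists when both are
#'   character vectors.
#' @return The enrichment p-value.
#' @export
hypergeom_enrich <- function(degs, set, universe_size, n_overlap = NULL) {
  n_degs <- if (is.character(degs)) length(unique(degs)) else degs
  n_set <- if (is.character(set)) length(unique(set)) else set
  if (is.null(n_overlap)) {
    if (!is.character(degs) || !is.character(set)) {
      stop("supply n_overlap when sizes, not lists, are given")
    }
    n_overlap <- length(intersect(tolower(unique(degs)),
                                  tolower(unique(set))))
  }
  if (n_set > universe_size || n_degs > universe_size ||
      n_overlap > min(n_degs, n_set)) {
    stop("inconsistent sizes: overlap ", n_overlap, ", degs ", n_degs,
         ", set ", n_set, ", universe ", universe_size)
  }
  stats::phyper(n_overlap - 1, n_set, universe_size - n_set, n_degs,
                lower.tail = FALSE)
}

#' Write an overlap profile
#'
#' @param profile an `overlap_profile`.
#' @param path output path stem; writes `<path>.csv` and `<path>.json`.
#' @export
write_overlap_profile <- function(profile, path) {
  utils::write.csv(as.data.frame(profile), paste0(path, ".csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(n_degs = attr(profile, "n_degs"),
         sets = as.data.frame(profile)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
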