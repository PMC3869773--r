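# Three-way overlap analysis between regulation/binding gene lists
# (e.g. PARP-14-regulated genes against externally supplied STAT6
# regulation and STAT6 binding lists), as generic set algebra.

#' Three-set Venn partition
#'
#' Partitions the union of three gene sets into the seven non-empty
#' membership regions (A, B, C, AB, AC, BC, ABC; each region exclusive of
#' the higher-order ones).  Member lists are emitted in lexicographic
#' order.
#'
#' @param a,b,c Character vectors (duplicates ignored) over a shared
#'   identifier namespace.
#' @param set_names Length-3 character vector naming the sets.
#' @return List with `region_counts` (named integer vector) and
#'   `region_members` (named list of sorted character vectors); region
#'   names are built from `set_names`.
#' @export
venn3 <- function(a, b, c, set_names = c("A", "B", "C")) {
  stopifnot(length(set_names) == 3L)
  a <- unique(as.character(a)); b <- unique(as.character(b))
  c <- unique(as.character(c))
  all_ids <- sort(unique(c(a, b, c)))
  in_a <- all_ids %in% a; in_b <- all_ids %in% b; in_c <- all_ids %in% c
  key <- paste0(ifelse(in_a, "A", ""), ifelse(in_b, "B", ""),
                ifelse(in_c, "C", ""))
  regions <- c("A", "B", "C", "AB", "AC", "BC", "ABC")
  members <- lapply(regions, function(r) all_ids[key == r])
  names(members) <- regions
  counts <- vapply(members, length, integer(1))
  pretty <- c(set_names,
              paste(set_names[1], set_names[2], sep = "&"),
              paste(set_names[1], set_names[3], sep = "&"),
              paste(set_names[2], set_names[3], sep = "&"),
              paste(set_names, collapse = "&"))
  list(region_counts = stats::setNames(counts, pretty),
       region_members = stats::setNames(members, pretty))
}

#' Harmonize gene identifiers between two lists
#'
#' Gene lists from different platforms rarely agree on symbol casing;
#' matching is case-insensitive by default, optionally preceded by an
#' alias mapping.  Unmapped ids are reported, never silently dropped.
#'
#' @param list_a,list_b Character vectors of gene identifiers.
#' @param alias Optional named character vector mapping source ids to
#'   canonical targets (applied to both lists before matching).  Two
#'   aliases sending one source id to different targets is an error.
#' @return List with `a` and `b` (canonicalized unique sets), `common`
#'   (ids present in both), and `unmapped_a` / `unmapped_b` (canonical
#'   ids present in only one list).
#' @export
harmonize_ids <- function(list_a, list_b, alias = NULL) {
  canon <- function(x) {
    x <- as.character(x)
    if (!is.null(alias)) {
      key <- toupper(names(alias))
      if (anyDuplicated(key)) {
        clash <- unique(key[duplicated(key)])
        bad <- vapply(clash, function(k)
          length(unique(toupper(alias[key == k]))) > 1L, logical(1))
        if (any(bad))
          .stop_fmt("ambiguous alias for id(s): %s",
                    paste(clash[bad], collapse = ", "))
      }
      hit <- match(toupper(x), key)
      x[!is.na(hit)] <- alias[hit[!is.na(hit)]]
    }
    unique(toupper(x))
  }
  ca <- canon(list_a); cb <- canon(list_b)
  common <- intersect(ca, cb)
  ua <- setdiff(ca, cb); ub <- setdiff(cb, ca)
  if (length(ua) || length(ub))
    message(sprintf("harmonize_ids: %d matched, %d unmapped in A, %d unmapped in B",
                    length(common), length(ua), length(ub)))
  list(a = ca, b = cb, common = sort(common),
       unmapped_a = sort(ua), unmapped_b = sort(ub))
}
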