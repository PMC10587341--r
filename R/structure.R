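# Locus-organization formulas.  The ordered segment-type sequence is
# compressed into runs "(TYPE)n" and tandem cassettes "[unit]k"; cassette
# copy-count variation at a single unit element is rendered as the shortest
# cyclic generator of the per-copy counts ("6/7" for counts 6,7,6), which
# makes the rendering invertible: expansion cycles the listed values.

# shortest prefix p of v such that v[i] == p[((i-1) mod |p|)+1]
cyclic_generator <- function(v) {
  for (L in seq_along(v)) {
    if (all(v == v[((seq_along(v) - 1L) %% L) + 1L])) return(v[seq_len(L)])
  }
  v
}

#' Build a locus structure with a compressed organization formula
#'
#' Consecutive same-type segments collapse to `(TYPE)n`; tandem cassettes
#' (the unit maximizing the number of contiguous copies, ties to the longer
#' unit, scanned greedily from the left) render as `[unit]k`, with per-copy
#' count variation allowed at one unit element. Cassettes whose elements all
#' have count 1 render with parentheses, e.g. `(IGLJ-IGLC)6`.
#'
#' @param segments `gene_segments` data.frame sorted in locus orientation.
#' @return object of class `locus_structure`: list with `locus`,
#'   `ordered_segments`, `cassettes`, `formula`.
#' @export
build_locus_structure <- function(segments) {
  if (nrow(segments) == 0L)
    return(structure(list(locus = NA_character_, ordered_segments = segments,
                          cassettes = list(), formula = ""),
                     class = "locus_structure"))
  locus <- segments$locus[1L]
  labels <- paste0(segments$locus, segments$seg_type)
  r <- rle(labels)
  toks <- data.frame(lab = r$values, count = r$lengths,
                     stringsAsFactors = FALSE)
  T <- nrow(toks)

  cassette_at <- function(i, u) {
    # count contiguous copies of the u-token unit starting at token i
    copies <- 1L
    unit <- toks$lab[i:(i + u - 1L)]
    while (i + (copies + 1L) * u - 1L <= T &&
           all(toks$lab[(i + copies * u):(i + (copies + 1L) * u - 1L)] == unit))
      copies <- copies + 1L
    if (copies < 2L) return(NULL)
    counts <- matrix(toks$count[i:(i + copies * u - 1L)], nrow = copies,
                     ncol = u, byrow = TRUE)
    varying <- sum(apply(counts, 2L, function(x) length(unique(x)) > 1L))
    if (varying > 1L) return(NULL)   # wider variation: not a cassette
    list(unit = unit, copies = copies, counts = counts)
  }

  elements <- character(0)
  cassettes <- list()
  i <- 1L
  while (i <= T) {
    best <- NULL; best_u <- 0L
    for (u in seq_len((T - i + 1L) %/% 2L)) {
      cand <- cassette_at(i, u)
      if (!is.null(cand) &&
          (is.null(best) || cand$copies > best$copies ||
           (cand$copies == best$copies && u > best_u))) {
        best <- cand; best_u <- u
      }
    }
    if (!is.null(best)) {
      inner <- vapply(seq_len(best_u), function(el) {
        cnts <- best$counts[, el]
        if (all(cnts == 1L)) best$unit[el]
        else if (length(unique(cnts)) == 1L)
          sprintf("(%s)%d", best$unit[el], cnts[1L])
        else sprintf("(%s)%s", best$unit[el],
                     paste(cyclic_generator(cnts), collapse = "/"))
      }, character(1L))
      open <- if (all(best$counts == 1L)) "(" else "["
      close <- if (open == "(") ")" else "]"
      elements <- c(elements, sprintf("%s%s%s%d", open,
                                      paste(inner, collapse = "-"),
                                      close, best$copies))
      cassettes[[length(cassettes) + 1L]] <-
        list(unit = best$unit, copies = best$copies, counts = best$counts,
             first_token = i)
      i <- i + best$copies * best_u
    } else {
      elements <- c(elements,
                    if (toks$count[i] == 1L) toks$lab[i]
                    else sprintf("(%s)%d", toks$lab[i], toks$count[i]))
      i <- i + 1L
    }
  }
  structure(list(locus = locus, ordered_segments = segments,
                 cassettes = cassettes,
                 formula = paste(elements, collapse = "-")),
            class = "locus_structure")
}

#' @export
print.locus_structure <- function(x, ...) {
  cat(sprintf("<locus_structure> %s: %s (%d segments)\n",
              x$locus, x$formula, nrow(x$ordered_segments)))
  invisible(x)
}

# split a formula on "-" at bracket depth 0
split_top <- function(s) {
  ch <- strsplit(s, "")[[1L]]
  depth <- 0L; parts <- character(0); cur <- character(0)
  for (c in ch) {
    if (c %in% c("(", "[")) depth <- depth + 1L
    if (c %in% c(")", "]")) depth <- depth - 1L
    if (c == "-" && depth == 0L) {
      parts <- c(parts, paste(cur, collapse = "")); cur <- character(0)
    } else cur <- c(cur, c)
  }
  c(parts, paste(cur, collapse = ""))
}

#' Expand a locus-organization formula to its segment-type sequence
#'
#' Inverse of the formula built by [build_locus_structure()]: `(X)n` expands
#' to n copies, `[unit]k` (or `(A-B)k`) repeats the unit k times, and a
#' varying count list `a/b` cycles through its values across cassette
#' copies.
#'
#' @param formula formula string.
#' @return character vector of segment-type labels, one per segment.
#' @export
expand_formula <- function(formula) {
  if (!nzchar(formula)) return(character(0))
  expand_el <- function(el, copy_index = 1L) {
    m <- regmatches(el, regexec("^\\(([^()-]+)\\)([0-9/]+)$", el))[[1L]]
    if (length(m)) {
      vals <- as.integer(strsplit(m[3L], "/", fixed = TRUE)[[1L]])
      n <- vals[((copy_index - 1L) %% length(vals)) + 1L]
      return(rep(m[2L], n))
    }
    mb <- regmatches(el, regexec("^[[(](.+)[])]([0-9]+)$", el))[[1L]]
    if (length(mb) && grepl("-", mb[2L], fixed = TRUE)) {
      inner <- split_top(mb[2L])
      k <- as.integer(mb[3L])
      return(unlist(lapply(seq_len(k), function(ci)
        unlist(lapply(inner, expand_el, copy_index = ci)))))
    }
    el  # bare label
  }
  unlist(lapply(split_top(formula), expand_el))
}

#' Summarize locus structures into a gene-count table
#'
#' Per-locus, per-type counts of total/F/P/ORF segments with row and column
#' sums (exact integer arithmetic), in the style of a gene-number table.
#'
#' @param structures list of `locus_structure` objects (one per locus).
#' @return list with `cells` (tidy per-locus per-type counts) and `table`
#'   (wide rendering, loci as columns).
#' @export
summarize_loci <- function(structures) {
  loci <- vapply(structures, function(s) s$locus, character(1L))
  if (anyDuplicated(loci)) imm_validation_error("duplicate locus in summary input")
  cells <- do.call(rbind, lapply(structures, function(s) {
    seg <- s$ordered_segments
    if (nrow(seg) == 0L) return(NULL)
    agg <- aggregate(list(n = seg$name),
                     by = list(seg_type = seg$seg_type,
                               functionality = seg$functionality),
                     FUN = length)
    out <- expand.grid(seg_type = c("V", "D", "J", "C"),
                       stringsAsFactors = FALSE)
    for (col in c("F", "P", "ORF")) {
      v <- agg$n[match(paste(out$seg_type, col),
                       paste(agg$seg_type, agg$functionality))]
      out[[col]] <- ifelse(is.na(v), 0L, v)
    }
    out$total <- out$F + out$P + out$ORF
    out$locus <- s$locus
    out[, c("locus", "seg_type", "total", "F", "P", "ORF")]
  }))
  aggregate_locus_counts(cells)
}

#' Aggregate a per-locus gene-count table
#'
#' Adds per-type row sums across loci, per-locus column sums, and the grand
#' totals, preserving the F/P/ORF partition.
#'
#' @param cells data.frame with columns `locus`, `seg_type`, `total`, `F`,
#'   `P`, `ORF` (one row per locus/type present).
#' @return list: `cells` (input, zero-filled), `type_totals` (per seg_type),
#'   `locus_totals` (per locus), `grand` (named totals), `table` (wide
#'   rendering "total (F/P/ORF)").
#' @export
aggregate_locus_counts <- function(cells) {
  if (is.null(cells) || nrow(cells) == 0L) {
    z <- data.frame(seg_type = c("V", "D", "J", "C"), total = 0L,
                    F = 0L, P = 0L, ORF = 0L)
    return(list(cells = data.frame(), type_totals = z,
                locus_totals = data.frame(),
                grand = c(total = 0L, F = 0L, P = 0L, ORF = 0L),
                table = data.frame()))
  }
  if (any(cells$total != cells$F + cells$P + cells$ORF))
    imm_validation_error("functionality partition violated: F+P+ORF != total")
  if (anyDuplicated(paste(cells$locus, cells$seg_type)))
    imm_validation_error("duplicate locus/type cell")
  num <- c("total", "F", "P", "ORF")
  type_totals <- aggregate(cells[num], by = list(seg_type = cells$seg_type), sum)
  type_totals <- type_totals[match(c("V", "D", "J", "C"), type_totals$seg_type), ]
  type_totals <- type_totals[!is.na(type_totals$seg_type), ]
  locus_totals <- aggregate(cells[num], by = list(locus = cells$locus), sum)
  grand <- vapply(cells[num], sum, numeric(1L))
  loci <- unique(cells$locus)
  wide <- data.frame(seg_type = type_totals$seg_type)
  for (lc in loci) {
    col <- vapply(wide$seg_type, function(ty) {
      r <- cells[cells$locus == lc & cells$seg_type == ty, ]
      if (nrow(r) == 0L) "NA"
      else sprintf("%d (%d/%d/%d)", r$total, r$F, r$P, r$ORF)
    }, character(1L))
    wide[[lc]] <- col
  }
  wide$Sum <- sprintf("%d (%d/%d/%d)", type_totals$total, type_totals$F,
                      type_totals$P, type_totals$ORF)
  list(cells = cells, type_totals = type_totals, locus_totals = locus_totals,
       grand = grand, table = wide)
}
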