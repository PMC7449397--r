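## Heptad register annotation, region extraction, mosaic-variant difference
## accounting, activity classification and per-column variant profiling.
##
## All residue coordinates exposed here are 1-based positions in the
## ungapped reference protein (position 1 = initiator M), the numbering used
## for landmarks such as I77, the heptad-8/9 quartet (105/107/108/111) and
## the hypervariable F134. Coiled coil boundaries and the stammer span are
## annotation inputs, not predictions.

#' Coiled coil heptad annotation
#'
#' Describes a coiled coil as `n_heptads` seven-residue repeats numbered
#' 1..n from the amino terminus, optionally interrupted by a three-residue
#' stammer inside one heptad. The spans must be consistent:
#' `7 * n_heptads + 3 * (stammer present) == cc_end - cc_start + 1`.
#'
#' @param cc_start,cc_end 1-based residue positions of the coil in the
#'   reference protein.
#' @param n_heptads Number of heptads.
#' @param stammer_heptad Heptad carrying the stammer, or `NULL` for none.
#' @return Object of class `cc_annotation`.
#' @export
coiled_coil_annotation <- function(cc_start, cc_end, n_heptads = 14L,
                                   stammer_heptad = 6L) {
  len <- cc_end - cc_start + 1L
  expected <- 7L * n_heptads + if (!is.null(stammer_heptad)) 3L else 0L
  if (len != expected)
    stop("inconsistent spans: coil covers ", len, " residues but ",
         n_heptads, " heptads", if (!is.null(stammer_heptad)) " + stammer",
         " require ", expected)
  structure(list(cc_start = as.integer(cc_start), cc_end = as.integer(cc_end),
                 n_heptads = as.integer(n_heptads),
                 stammer_heptad = if (is.null(stammer_heptad)) NULL
                                  else as.integer(stammer_heptad)),
            class = "cc_annotation")
}

#' Per-residue heptad register table
#'
#' Walks the coil from its amino terminus assigning register letters a-g
#' within each heptad; the three stammer residues (inserted after position
#' d of the stammer heptad) are marked `"stm"`.
#'
#' @param annotation A [coiled_coil_annotation()].
#' @return data.frame with columns `position` (reference coordinates),
#'   `heptad`, `letter`.
#' @export
assign_register <- function(annotation) {
  stopifnot(inherits(annotation, "cc_annotation"))
  heptad <- integer(0); letter <- character(0)
  for (h in seq_len(annotation$n_heptads)) {
    if (!is.null(annotation$stammer_heptad) && h == annotation$stammer_heptad) {
      heptad <- c(heptad, rep(h, 10L))
      letter <- c(letter, c("a", "b", "c", "d", "stm", "stm", "stm",
                            "e", "f", "g"))
    } else {
      heptad <- c(heptad, rep(h, 7L))
      letter <- c(letter, letters[1:7])
    }
  }
  data.frame(position = annotation$cc_start + seq_along(heptad) - 1L,
             heptad = heptad, letter = letter, stringsAsFactors = FALSE)
}

#' Heptad containing a reference position
#'
#' @param register Register table from [assign_register()].
#' @param position 1-based reference position(s).
#' @return Integer heptad number(s); `NA` outside the coil.
#' @export
heptad_of <- function(register, position) {
  register$heptad[match(position, register$position)]
}

#' Reference positions of one or more heptads
#'
#' @param register Register table from [assign_register()].
#' @param heptads Heptad numbers.
#' @return Integer vector of reference positions.
#' @export
positions_of <- function(register, heptads) {
  register$position[register$heptad %in% heptads]
}

## Difference accounting ------------------------------------------------------

seq_chars <- function(x) {
  if (length(x) == 1L && nchar(x) > 1L) strsplit(toupper(x), "")[[1]]
  else toupper(x)
}

restrict_region <- function(pos, region) {
  if (is.null(region)) return(pos)
  pos[pos %in% region_positions(region)]
}

region_positions <- function(region) {
  if (is.null(region)) stop("no region")
  if (length(region) == 2L && is.numeric(region) && region[2L] >= region[1L] &&
      all(region == as.integer(region)) && length(region) == 2L)
    return(seq.int(region[1L], region[2L]))
  as.integer(region)
}

#' Positions at which two aligned proteins differ
#'
#' Reports 1-based positions where both sequences carry standard residues
#' and the residues differ; positions holding `-`, `O` or `X` in either
#' sequence are never counted as differences.
#'
#' @param a,b Equal-length (aligned) protein strings or character vectors.
#' @param region Optional restriction: either `c(start, end)` or an
#'   explicit vector of positions.
#' @return data.frame with columns `position`, `a`, `b`.
#' @export
diff_positions <- function(a, b, region = NULL) {
  av <- seq_chars(a); bv <- seq_chars(b)
  if (length(av) != length(bv))
    stop("length mismatch: ", length(av), " vs ", length(bv))
  pos <- which(av %in% AA20 & bv %in% AA20 & av != bv)
  pos <- restrict_region(pos, region)
  data.frame(position = pos, a = av[pos], b = bv[pos],
             stringsAsFactors = FALSE)
}

#' Count ancestral residues carried by a variant
#'
#' Counts region positions where the variant matches the ancestral parent
#' at a site where the two parents differ. The complementary
#' [modern_residue_count()] satisfies
#' `ancestral + modern == nrow(diff_positions(modern, ancestral, region))`
#' for variants built purely from the two parents.
#'
#' @param variant,modern,ancestral Aligned protein strings.
#' @param region Optional region restriction (see [diff_positions()]).
#' @return Integer count.
#' @export
ancestral_residue_count <- function(variant, modern, ancestral,
                                    region = NULL) {
  v <- seq_chars(variant)
  d <- diff_positions(modern, ancestral, region)
  sum(v[d$position] == d$b)
}

#' @rdname ancestral_residue_count
#' @export
modern_residue_count <- function(variant, modern, ancestral, region = NULL) {
  v <- seq_chars(variant)
  d <- diff_positions(modern, ancestral, region)
  sum(v[d$position] == d$a)
}

#' Classify retrotransposition activity
#'
#' Activity is expressed as percent of the modern reference element.
#' Variants at >= 80% are `active`, below 5% `inactive`; the open interval
#' `[5, 80)` is reported as `intermediate` rather than forced into either
#' class.
#'
#' @param activity_pct Percent activity (vectorized), `>= 0`.
#' @return Character vector over `{"active", "inactive", "intermediate"}`.
#' @export
classify_activity <- function(activity_pct) {
  if (any(activity_pct < 0, na.rm = TRUE)) stop("activity must be >= 0")
  out <- ifelse(activity_pct >= 80, "active",
                ifelse(activity_pct < 5, "inactive", "intermediate"))
  out[is.na(activity_pct)] <- NA_character_
  out
}

#' Residue frequency profile of one alignment column
#'
#' Residue frequencies over informative rows at a reference position, with
#' a hypervariability flag raised when the non-consensus fraction reaches
#' `threshold` (e.g. the F134 column of a young family where ~10% of copies
#' carry V or S).
#'
#' @param peptides Protein alignment.
#' @param position 1-based reference position.
#' @param ref Optional id of the reference record in the alignment; when
#'   given, `position` is counted along its ungapped sequence and mapped to
#'   the alignment column, otherwise `position` is used as the column index
#'   directly.
#' @param threshold Non-consensus fraction at or above which the column is
#'   flagged.
#' @return List: `position`, `column`, `frequencies` (named, decreasing),
#'   `non_consensus`, `flagged`.
#' @export
column_profile <- function(peptides, position, ref = NULL, threshold = 0.05) {
  m <- as_alignment_matrix(peptides)
  if (!is.null(ref)) {
    if (!ref %in% rownames(m)) stop("reference id '", ref, "' not found")
    ungapped <- which(m[ref, ] != "-")
    if (position < 1L || position > length(ungapped))
      stop("position ", position, " outside reference of length ",
           length(ungapped))
    col_idx <- ungapped[position]
  } else {
    if (position < 1L || position > ncol(m))
      stop("position ", position, " outside alignment of width ", ncol(m))
    col_idx <- position
  }
  obs <- m[, col_idx][m[, col_idx] %in% AA20]
  if (length(obs) == 0L)
    return(list(position = position, column = col_idx,
                frequencies = stats::setNames(numeric(0), character(0)),
                non_consensus = NA_real_, flagged = FALSE))
  tab <- sort(table(obs) / length(obs), decreasing = TRUE)
  freqs <- stats::setNames(as.numeric(tab), names(tab))
  non_consensus <- 1 - freqs[1L]
  list(position = position, column = col_idx, frequencies = freqs,
       non_consensus = unname(non_consensus),
       flagged = unname(non_consensus >= threshold))
}

## Mosaic variants ------------------------------------------------------------

parse_substitutions <- function(subs) {
  if (is.null(subs) || length(subs) == 0L ||
      (length(subs) == 1L && (is.na(subs) || subs == "")))
    return(data.frame(position = integer(0), from = character(0),
                      to = character(0), stringsAsFactors = FALSE))
  if (length(subs) == 1L) subs <- strsplit(subs, ";", fixed = TRUE)[[1]]
  mt <- regmatches(subs, regexec("^([A-Z])([0-9]+)([A-Z])$", subs))
  bad <- vapply(mt, length, integer(1)) != 4L
  if (any(bad)) stop("malformed substitution: ", subs[bad][1L])
  data.frame(position = as.integer(vapply(mt, `[`, character(1), 3L)),
             from = vapply(mt, `[`, character(1), 2L),
             to = vapply(mt, `[`, character(1), 4L),
             stringsAsFactors = FALSE)
}

#' Build a mosaic variant from two parents
#'
#' Assembles a protein from region-wise parental composition (the `151`,
#' `511`, ... naming: one digit per region, modern or ancestral), then
#' applies explicit point substitutions such as `"I77L"`. Substitutions are
#' validated against the assembled sequence, so a variant is always
#' reconstructible from parents + composition + substitutions.
#'
#' @param modern,ancestral Aligned parent protein strings.
#' @param composition data.frame with columns `start`, `end`, `parent`
#'   (`"modern"` or `"ancestral"`); regions must tile the whole protein.
#' @param substitutions Character vector (or `";"`-separated string) of
#'   `"<from><pos><to>"` substitutions, or `NULL`.
#' @return Protein string.
#' @export
build_mosaic <- function(modern, ancestral, composition,
                         substitutions = NULL) {
  mv <- seq_chars(modern); av <- seq_chars(ancestral)
  if (length(mv) != length(av)) stop("parents must be aligned")
  comp <- composition[order(composition$start), , drop = FALSE]
  covered <- unlist(Map(seq.int, comp$start, comp$end))
  if (!identical(sort(covered), seq_along(mv)))
    stop("composition regions must tile positions 1..", length(mv))
  out <- mv
  for (i in seq_len(nrow(comp))) {
    idx <- seq.int(comp$start[i], comp$end[i])
    out[idx] <- switch(match.arg(comp$parent[i], c("modern", "ancestral")),
                       modern = mv[idx], ancestral = av[idx])
  }
  subs <- parse_substitutions(substitutions)
  for (i in seq_len(nrow(subs))) {
    p <- subs$position[i]
    if (out[p] != subs$from[i])
      stop("substitution ", subs$from[i], p, subs$to[i],
           " does not match assembled residue '", out[p], "'")
    out[p] <- subs$to[i]
  }
  paste0(out, collapse = "")
}

#' Read a mosaic-variant table
#'
#' TSV with columns `name`, `composition` (comma-separated region parents,
#' e.g. `"modern,ancestral,modern"`), `substitutions` (`";"`-separated or
#' empty), `activity_pct`, `expression_tested`.
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_variant_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, na.strings = c("NA", ""))
  needed <- c("name", "composition", "substitutions", "activity_pct")
  if (!all(needed %in% names(df)))
    stop("variant table must have columns: ", paste(needed, collapse = ", "))
  df
}
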