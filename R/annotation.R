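#' Parse a UCSC-style cytoBand file
#'
#' Reads the five-column tab-separated cytoBand format (`chrom`, `chromStart`,
#' `chromEnd`, `name`, `gieStain`) into a validated cytoband map. Coordinates
#' are 0-based, half-open, matching the UCSC dialect: a band `[start, end)`
#' contains `start` but not `end`. The `chr` prefix is stripped from
#' chromosome labels and the full band label is formed by concatenating the
#' chromosome and the band name (`chr1` + `p31.2` -> `1p31.2`). Sex
#' chromosomes keep their letters (`X`, `Y`).
#'
#' @param file Path to a cytoBand file, or a connection. Lines may omit the
#'   stain column.
#' @return A `cytoband_map`: a `data.frame` with columns `chromosome`,
#'   `start`, `end`, `band`, `stain`, ordered by chromosome and start.
#' @seealso [locate_band()], [annotate_probes()]
#' @export
parse_cytoband_file <- function(file) {
  lines <- readLines(file)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty cytoband file")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 4L)) {
    stop("cytoband lines with fewer than 4 fields: ",
         paste(which(nf < 4L), collapse = ", "))
  }
  chrom <- sub("^chr", "", vapply(fields, `[[`, "", 1L))
  start <- as.numeric(vapply(fields, `[[`, "", 2L))
  end <- as.numeric(vapply(fields, `[[`, "", 3L))
  name <- vapply(fields, `[[`, "", 4L)
  stain <- vapply(fields, function(f) if (length(f) >= 5L) f[[5L]] else NA_character_, "")
  if (any(is.na(start)) || any(is.na(end))) stop("non-numeric cytoband coordinates")
  map <- data.frame(chromosome = chrom, start = start, end = end,
                    band = paste0(chrom, name), stain = stain,
                    stringsAsFactors = FALSE)
  validate_cytoband_map(map)
}

#' Validate a cytoband map
#'
#' Checks the interval invariants: within each chromosome the bands must have
#' `start < end`, be sortable without overlap, and carry unique labels.
#'
#' @param map A `data.frame` with columns `chromosome`, `start`, `end`, `band`
#'   (and optionally `stain`).
#' @return The map, sorted by chromosome and start, with class `cytoband_map`.
#' @export
validate_cytoband_map <- function(map) {
  stopifnot(is.data.frame(map),
            all(c("chromosome", "start", "end", "band") %in% names(map)))
  if (!"stain" %in% names(map)) map$stain <- NA_character_
  bad <- which(map$start >= map$end)
  if (length(bad)) {
    stop("cytoband intervals with start >= end at rows: ",
         paste(bad, collapse = ", "))
  }
  map <- map[order(chromosome_order(map$chromosome), map$start), , drop = FALSE]
  for (chr in unique(map$chromosome)) {
    sub <- map[map$chromosome == chr, , drop = FALSE]
    if (anyDuplicated(sub$band)) {
      stop("duplicate band labels on chromosome ", chr, ": ",
           paste(unique(sub$band[duplicated(sub$band)]), collapse = ", "))
    }
    if (nrow(sub) > 1L) {
      ov <- which(sub$start[-1L] < sub$end[-nrow(sub)])
      if (length(ov)) {
        stop("overlapping cytoband intervals on chromosome ", chr,
             " involving bands: ",
             paste(sub$band[c(ov, ov + 1L)], collapse = ", "))
      }
    }
  }
  rownames(map) <- NULL
  class(map) <- c("cytoband_map", "data.frame")
  map
}

#' Canonical chromosome ordering
#'
#' Orders autosome labels numerically, then X, then Y, then anything else
#' alphabetically. Used for genomic sorting and deterministic tie-breaks.
#'
#' @param chromosome Character vector of chromosome labels (no `chr` prefix).
#' @return An integer-compatible numeric rank usable in [order()].
#' @export
chromosome_order <- function(chromosome) {
  n <- suppressWarnings(as.numeric(chromosome))
  rank <- ifelse(!is.na(n), n,
          ifelse(chromosome == "X", 100,
          ifelse(chromosome == "Y", 101,
                 102 + as.numeric(factor(chromosome)))))
  rank
}

#' Locate genomic positions on a cytoband map
#'
#' Returns, for each (chromosome, position) pair, the label of the band whose
#' half-open interval `[start, end)` contains the position, or `"unmapped"`
#' when no band does. Unknown chromosomes map to `"unmapped"` as well (with a
#' single message, not an error).
#'
#' @param chromosome Character vector of chromosome labels.
#' @param position Numeric vector of 0-based positions (recycled against
#'   `chromosome` in the usual way; both must have the same length).
#' @param map A `cytoband_map`.
#' @return Character vector of band labels, `"unmapped"` where uncovered.
#' @export
locate_band <- function(chromosome, position, map) {
  stopifnot(length(chromosome) == length(position), all(position >= 0))
  out <- rep("unmapped", length(chromosome))
  unknown <- setdiff(unique(chromosome), unique(map$chromosome))
  if (length(unknown)) {
    message("chromosomes absent from cytoband map treated as unmapped: ",
            paste(unknown, collapse = ", "))
  }
  for (chr in intersect(unique(chromosome), unique(map$chromosome))) {
    sub <- map[map$chromosome == chr, , drop = FALSE]
    idx <- which(chromosome == chr)
    # map is sorted and non-overlapping; findInterval on starts, then verify
    # the position sits left of that interval's end
    hit <- findInterval(position[idx], sub$start)
    ok <- hit >= 1L & position[idx] < sub$end[pmax(hit, 1L)]
    out[idx[ok]] <- sub$band[hit[ok]]
  }
  out
}

#' Annotate probes with cytogenetic bands
#'
#' Fills a `band` column using [locate_band()]. Rows are preserved in number
#' and order; probes outside every band (or on chromosomes absent from the
#' map) get the explicit marker `"unmapped"`.
#'
#' @param probes A `data.frame` with at least `chromosome` and `position`
#'   columns; typically also `probe_id`, `gene_symbol`, `rna_class`.
#' @param map A `cytoband_map`.
#' @return The input with a `band` column (replaced if already present).
#' @export
annotate_probes <- function(probes, map) {
  stopifnot(is.data.frame(probes),
            all(c("chromosome", "position") %in% names(probes)))
  if (nrow(probes) == 0L) {
    probes$band <- character(0)
    return(probes)
  }
  if ("probe_id" %in% names(probes) && anyDuplicated(probes$probe_id)) {
    stop("duplicate probe_id values")
  }
  probes$band <- locate_band(probes$chromosome, probes$position, map)
  probes
}

#' Read a probe annotation table
#'
#' @param file Path to a tab-separated file with header columns `probe_id`,
#'   `gene_symbol`, `rna_class`, `chromosome`, `position` (a `band` column, if
#'   present, is kept).
#' @return A `data.frame` of probe annotations.
#' @export
read_probe_annotation <- function(file) {
  ann <- utils::read.delim(file, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("probe_id", "gene_symbol", "rna_class", "chromosome", "position")
  miss <- setdiff(need, names(ann))
  if (length(miss)) stop("annotation file lacks columns: ", paste(miss, collapse = ", "))
  ann$chromosome <- sub("^chr", "", as.character(ann$chromosome))
  ann
}
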