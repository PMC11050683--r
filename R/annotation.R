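# Bundled annotation tables for the FGFR2 tyrosine kinase domain (UniProt
# P21802 numbering): functional regions, the curated PDB entry set with
# activation states and mutations, disease classes, and AlphaMissense-style
# pathogenicity records. Plus the operations that map positions to regions,
# attach labels to traces, and tabulate pathogenicity hits.

extdata <- function(file) {
  path <- system.file("extdata", file, package = "fgfr2dyn")
  if (!nzchar(path)) path <- file.path("inst", "extdata", file)
  path
}

read_table_tsv <- function(file) {
  utils::read.delim(extdata(file), stringsAsFactors = FALSE,
                    check.names = FALSE, colClasses = "character")
}

#' Functional regions of the FGFR2 tyrosine kinase domain
#'
#' One row per region: `symbol` (B, N, G, H, K, C, T, A, O), `name` and
#' `ranges`, a comma-separated list of inclusive residue intervals and
#' singletons (e.g. `"643-649,651-664"` for the activation loop). `O`
#' ("Others") covers every position outside the named regions.
#'
#' @return data.frame with columns `symbol`, `name`, `ranges`.
#' @export
fgfr2_regions <- function() read_table_tsv("regions.tsv")

parse_ranges <- function(ranges) {
  if (ranges == "-") return(integer())
  parts <- strsplit(ranges, ",", fixed = TRUE)[[1]]
  unlist(lapply(parts, function(p) {
    bounds <- as.integer(strsplit(p, "-", fixed = TRUE)[[1]])
    if (length(bounds) == 2L) seq(bounds[1], bounds[2]) else bounds
  }))
}

region_position_map <- function() {
  regions <- fgfr2_regions()
  positions <- lapply(regions$ranges, parse_ranges)
  data.frame(position = unlist(positions),
             symbol = rep(regions$symbol, lengths(positions)),
             stringsAsFactors = FALSE)
}

#' Map residue positions to functional region symbols
#'
#' Every position maps to exactly one symbol; positions outside all named
#' region ranges map to `"O"` (Others).
#'
#' @param position integer vector of residue numbers (>= 1).
#' @return Character vector of region symbols, same length as `position`.
#' @examples
#' assign_region(c(564, 650, 659, 700))  # "G" "T" "A" "O"
#' @export
assign_region <- function(position) {
  position <- as.integer(position)
  if (any(position < 1L, na.rm = TRUE)) stop("positions must be >= 1")
  map <- region_position_map()
  out <- map$symbol[match(position, map$position)]
  out[is.na(out) & !is.na(position)] <- "O"
  out
}

#' Curated FGFR2-TKD structure table
#'
#' The PDB entry set analyzed by the package: per entry, its mutation
#' string (`"WT"`, a single substitution such as `"K659N"`, a slash-joined
#' pair, or `"Multiple"` for heavily mutated constructs), the literature
#' region name, activation status, associated disease class(es), and the
#' chains removed during curation with the verbatim removal note. Two
#' entries are excluded at the manifest level (unusable source data) and
#' only returned when `include_excluded = TRUE`.
#'
#' @param include_excluded also return manifest-level exclusions.
#' @return data.frame; see `inst/extdata/structures.tsv` for columns.
#' @export
fgfr2_structures <- function(include_excluded = FALSE) {
  tab <- read_table_tsv("structures.tsv")
  if (!include_excluded) tab <- tab[tab$excluded == "no", , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Disease classes of FGFR2-TKD variants
#'
#' Variant-to-disease records curated from OMIM/COSMIC/HGMD: disease class
#' abbreviation (`CS`, `PS`, `UCS`, `LADD1`, `CC`, `EC`, `LC`), full
#' disease name, category, the mutation, and associated PDB entries
#' (`"-"` for variants with no experimentally resolved structure).
#'
#' @return data.frame with columns `class`, `disease`, `category`,
#'   `subcategory`, `mutation`, `entries`.
#' @export
fgfr2_diseases <- function() read_table_tsv("diseases.tsv")

#' Pathogenicity records for FGFR2 variants
#'
#' Sixteen single-substitution variants with a predicted pathogenicity
#' score in `[0, 1]`, the discretized call, the known disease class
#' (`"-"` when none is documented) and the recorded hit indicator.
#'
#' @return data.frame with columns `mutation`, `entries`, `score`
#'   (numeric), `call`, `disease`, `hit` (integer).
#' @export
fgfr2_pathogenicity <- function() {
  tab <- read_table_tsv("pathogenicity.tsv")
  tab$score <- as.numeric(tab$score)
  tab$hit <- as.integer(tab$hit)
  tab
}

#' Required residue positions for chain curation
#'
#' The union of all functional-region ranges: a chain missing any of these
#' positions is removed before ensemble assembly.
#'
#' @return Sorted integer vector of residue numbers.
#' @export
fgfr2_required_positions <- function() {
  sort(unique(region_position_map()$position))
}

parse_mutations <- function(mutation) {
  if (mutation %in% c("WT", "-", "", "Multiple")) return(
    data.frame(position = integer(), from = character(), to = character(),
               stringsAsFactors = FALSE))
  parts <- strsplit(mutation, "/", fixed = TRUE)[[1]]
  ok <- grepl("^[A-Z][0-9]+[A-Z]$", parts)
  parts <- parts[ok]
  data.frame(position = as.integer(gsub("[A-Z]", "", parts)),
             from = substr(parts, 1, 1),
             to = substring(parts, nchar(parts)),
             stringsAsFactors = FALSE)
}

#' Attach state, mutation and disease labels to traces
#'
#' Looks each trace's PDB entry up in the structure table and returns one
#' labeled row per trace. Mutation positions are mapped onto functional
#' region symbols with [assign_region()]; the table's literature region
#' names are carried verbatim alongside.
#'
#' @param trace_ids character vector of `"ENTRY:CHAIN"` identifiers (plain
#'   entry ids also accepted).
#' @param structures structure table, defaulting to [fgfr2_structures()].
#' @return data.frame with columns `trace_id`, `entry`, `chain`,
#'   `mutation`, `positions` (comma-joined), `region_symbols`
#'   (comma-joined, `"-"` for wildtype), `region_name`, `status`,
#'   `disease`, `wildtype` (logical).
#' @export
label_traces <- function(trace_ids, structures = fgfr2_structures()) {
  parts <- strsplit(trace_ids, ":", fixed = TRUE)
  entry <- toupper(vapply(parts, `[`, "", 1L))
  chain <- vapply(parts, function(p) if (length(p) > 1L) p[2] else "", "")
  idx <- match(entry, toupper(structures$entry))
  if (anyNA(idx))
    stop("unknown entries: ", paste(unique(entry[is.na(idx)]), collapse = ", "))
  rows <- lapply(seq_along(trace_ids), function(i) {
    rec <- structures[idx[i], ]
    muts <- parse_mutations(rec$mutation)
    symbols <- if (nrow(muts)) assign_region(muts$position) else character()
    data.frame(trace_id = trace_ids[i], entry = entry[i], chain = chain[i],
               mutation = rec$mutation,
               positions = if (nrow(muts))
                 paste(muts$position, collapse = ",") else "-",
               region_symbols = if (length(symbols))
                 paste(symbols, collapse = ",") else "-",
               region_name = rec$region_name, status = rec$status,
               disease = rec$disease,
               wildtype = rec$mutation == "WT",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Tabulate pathogenicity hits
#'
#' A record counts as a hit when its discretized call is
#' `"likely pathogenic"` and a disease association is documented for the
#' variant. Returns the hit count, the record total and the hit
#' percentage.
#'
#' @param records pathogenicity table (default [fgfr2_pathogenicity()]);
#'   needs columns `call` and `disease`.
#' @return List with `hits`, `total`, `percentage`.
#' @export
pathogenicity_hits <- function(records = fgfr2_pathogenicity()) {
  if (is.null(nrow(records)) || nrow(records) == 0L)
    stop("no pathogenicity records supplied")
  has_disease <- !(records$disease %in% c("-", "", NA))
  hit <- records$call == "likely pathogenic" & has_disease
  list(hits = sum(hit), total = nrow(records),
       percentage = 100 * sum(hit) / nrow(records))
}
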