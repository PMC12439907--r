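#' @importFrom data.table fread fwrite setnames setorder setDT setattr
#' @importFrom data.table fifelse rbindlist := .N .SD
NULL

# Default synonyms accepted for each canonical column. `modkit extract`
# style headers are covered; users can override via `column_map`.
.default_column_map <- list(
  read_id    = c("read_id", "readid", "read", "read_name", "query_name"),
  contig     = c("contig", "chrom", "chromosome", "chr", "ref", "seqnames"),
  position   = c("position", "pos", "ref_position", "start", "forward_read_position"),
  strand     = c("strand", "ref_strand"),
  call       = c("call", "call_code", "mod_call", "methylated", "mod"),
  confidence = c("confidence", "call_prob", "prob", "qual", "call_probability")
)

.norm_call <- function(x) {
  if (is.logical(x)) return(as.integer(x))
  if (is.numeric(x)) return(as.integer(x != 0))
  x <- tolower(as.character(x))
  out <- rep(NA_integer_, length(x))
  out[x %in% c("m", "meth", "methylated", "mod", "modified", "1", "true")] <- 1L
  out[x %in% c("u", "unmeth", "unmethylated", "-", "canonical", "unmodified",
               "0", "false")] <- 0L
  if (anyNA(out)) {
    stop("unrecognised call values: ",
         paste(utils::head(unique(x[is.na(out)]), 3), collapse = ", "))
  }
  out
}

#' Read per-read GpC methylation calls from a TSV file
#'
#' Reads a tab-separated table with one row per (read, GpC site) call, as
#' produced by `modkit extract`-style exporters, keeping calls inside a
#' region with sufficient call confidence. Low-confidence calls are treated
#' as missing data (dropped), not as unmethylated.
#'
#' @param path Path to a TSV file with a header.
#' @param region Optional [region_spec()]; only calls with matching contig
#'   and `region$start <= position < region$end` are kept.
#' @param min_confidence Calls with confidence below this are dropped
#'   (default 0 keeps everything). Ignored when the file has no
#'   confidence column (confidence is then assumed 1).
#' @param column_map Named list overriding the accepted column-name
#'   synonyms for `read_id`, `contig`, `position`, `strand`, `call`,
#'   `confidence`.
#' @return A `data.table` with columns `read_id`, `contig`, `position`,
#'   `strand`, `call` (integer 0/1), `confidence`, ordered by
#'   (`read_id`, `position`), at most one row per (read_id, contig,
#'   position). Attribute `"call_log"` records row counts dropped at each
#'   step.
#' @export
read_methyl_calls <- function(path, region = NULL, min_confidence = 0,
                              column_map = NULL) {
  cmap <- .default_column_map
  if (!is.null(column_map)) {
    for (nm in names(column_map)) cmap[[nm]] <- column_map[[nm]]
  }
  dt <- fread(path, sep = "\t", header = TRUE)
  have <- tolower(names(dt))
  pick <- function(canon, required = TRUE) {
    hit <- which(have %in% tolower(cmap[[canon]]))
    if (!length(hit)) {
      if (required) {
        stop("input is missing a '", canon, "' column (accepted names: ",
             paste(cmap[[canon]], collapse = ", "), ")")
      }
      return(NA_integer_)
    }
    hit[1L]
  }
  idx <- c(read_id = pick("read_id"), contig = pick("contig"),
           position = pick("position"), strand = pick("strand"),
           call = pick("call"))
  conf_idx <- pick("confidence", required = FALSE)
  out <- dt[, idx, with = FALSE]
  setnames(out, names(idx))
  out[, `:=`(read_id = as.character(read_id),
             contig = as.character(contig),
             position = as.numeric(position),
             strand = as.character(strand),
             call = .norm_call(call))]
  out[, confidence := if (is.na(conf_idx)) 1 else as.numeric(dt[[conf_idx]])]
  if (any(out$confidence < 0 | out$confidence > 1, na.rm = TRUE)) {
    stop("confidence values outside [0, 1]")
  }

  log <- list(n_rows = nrow(out))
  if (!is.null(region)) {
    stopifnot(inherits(region, "region_spec"))
    out <- out[contig == region$contig & position >= region$start &
                 position < region$end]
  }
  log$n_in_region <- nrow(out)
  out <- out[confidence >= min_confidence]
  log$n_confident <- nrow(out)
  setorder(out, read_id, position)
  out <- unique(out, by = c("read_id", "contig", "position"))
  log$n_unique <- nrow(out)
  setattr(out, "call_log", log)
  out[]
}

#' Write the phasing result bundle to disk
#'
#' Writes, under a common path prefix:
#' * `<prefix>.assignments.tsv` — one row per input read with its label
#'   (`0..t-1`, `FULLY_METH`, `FULLY_UNMETH`, `UNASSIGNED` or `FILTERED`),
#'   masked distance to the chosen series and shared-bin count;
#' * `<prefix>.series<k>.bedGraph` — per-bin mean methylation of series
#'   `k` (0-based), bin-aligned, sorted, non-overlapping;
#' * `<prefix>.report.json` — parameter echo, seed, per-stage read counts
#'   and series proportions.
#'
#' @param bundle A `phasing_bundle` from [phase_reads()].
#' @param prefix Output path prefix (directories must exist).
#' @return Invisibly, the character vector of files written.
#' @export
write_assignments <- function(bundle, prefix) {
  stopifnot(inherits(bundle, "phasing_bundle"))
  paths <- character(0)

  tsv <- file.path(paste0(prefix, ".assignments.tsv"))
  asn <- data.table::copy(bundle$assignments)
  asn[, distance := ifelse(is.na(distance), "NA", sprintf("%.10g", distance))]
  fwrite(asn, tsv, sep = "\t", quote = FALSE)
  paths <- c(paths, tsv)

  grid <- bundle$grid
  t <- nrow(bundle$series$profile)
  for (k in seq_len(t)) {
    prof <- bundle$series$profile[k, ]
    keep <- !is.na(prof)
    bg <- data.table::data.table(
      chrom = grid$region$contig,
      start = as.integer(grid$start[keep]),
      end = as.integer(grid$end[keep]),
      value = sprintf("%.6g", prof[keep]))
    f <- paste0(prefix, ".series", k - 1L, ".bedGraph")
    header <- sprintf(
      "track type=bedGraph name=series_%d description=\"mean GpC methylation, cluster series %d\"",
      k - 1L, k - 1L)
    writeLines(header, f)
    fwrite(bg, f, sep = "\t", quote = FALSE, col.names = FALSE,
           append = TRUE)
    paths <- c(paths, f)
  }

  rep_file <- paste0(prefix, ".report.json")
  report <- list(
    parameters = bundle$params,
    seed = bundle$params$seed,
    counts = bundle$counts,
    series = list(
      n_series = t,
      reads = bundle$series$n_reads,
      proportion = bundle$series$proportion),
    metadata = list(written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                    package = "nomephase",
                    version = as.character(utils::packageVersion("nomephase"))))
  jsonlite::write_json(report, rep_file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  paths <- c(paths, rep_file)
  invisible(paths)
}

#' Read back an assignments TSV written by [write_assignments()]
#'
#' @param path Path to an `.assignments.tsv` file.
#' @return A `data.table` with `read_id`, `label`, `distance`,
#'   `n_shared_bins`.
#' @export
read_assignments <- function(path) {
  dt <- fread(path, sep = "\t", header = TRUE,
              colClasses = list(character = c("read_id", "label")))
  dt[, distance := suppressWarnings(as.numeric(distance))]
  dt[]
}
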