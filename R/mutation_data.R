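# Parsing, validation and I/O for ProTherm-like mutation tables.
#
# A record is one experimental measurement: a protein code, one or two amino
# acid substitutions written <WT><POS><MUT> (e.g. "A23S", "A23S+F45L"), and
# the observed unfolding free-energy change ddG in kcal/mol. The stored sign
# convention is positive = stabilizing, negative = destabilizing; ddG is kept
# exactly as given in the input.

#' Canonical one-letter amino-acid alphabet
#' @export
AMINO_ACIDS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Construct a single substitution event
#'
#' @param wt one-letter wild-type residue.
#' @param position 1-based sequence position (positive integer).
#' @param mut one-letter mutant residue, different from `wt`.
#' @return a `mutation_event` list with fields `wt`, `position`, `mut`.
#' @examples
#' mutation_event("A", 23, "S")
#' @export
mutation_event <- function(wt, position, mut) {
  if (!is.character(wt) || !wt %in% AMINO_ACIDS) {
    stop("non-canonical wild-type residue: ", deparse(wt), call. = FALSE)
  }
  if (!is.character(mut) || !mut %in% AMINO_ACIDS) {
    stop("non-canonical mutant residue: ", deparse(mut), call. = FALSE)
  }
  if (wt == mut) {
    stop("silent substitution (wild type equals mutant): ",
         wt, position, mut, call. = FALSE)
  }
  position <- as.integer(position)
  if (is.na(position) || position < 1L) {
    stop("position must be a positive integer, got ", position, call. = FALSE)
  }
  structure(list(wt = wt, position = position, mut = mut),
            class = "mutation_event")
}

#' Parse a mutation notation string into substitution events
#'
#' Accepts one or two events in `<WT><POS><MUT>` notation joined by `"+"` or
#' `","`, e.g. `"A23S"` or `"A23S+F45L"`.
#'
#' @param s non-empty mutation string.
#' @return list of 1 or 2 `mutation_event`s, in input order.
#' @examples
#' parse_mutation_string("A23S")
#' parse_mutation_string("A23S+F45L")
#' @export
parse_mutation_string <- function(s) {
  if (!is.character(s) || length(s) != 1L || is.na(s) || !nzchar(s)) {
    stop("mutation string must be a non-empty character scalar", call. = FALSE)
  }
  tokens <- strsplit(s, "[+,]")[[1]]
  tokens <- trimws(tokens)
  if (length(tokens) > 2L) {
    stop("more than two substitution events in ", sQuote(s), call. = FALSE)
  }
  if (any(!nzchar(tokens)) || length(tokens) == 0L) {
    stop("empty substitution token in ", sQuote(s), call. = FALSE)
  }
  lapply(tokens, function(tok) {
    m <- regmatches(tok, regexec("^([A-Za-z])([0-9]+)([A-Za-z])$", tok))[[1]]
    if (length(m) != 4L) {
      stop("malformed mutation token ", sQuote(tok), call. = FALSE)
    }
    wt <- toupper(m[2]); mut <- toupper(m[4])
    if (!wt %in% AMINO_ACIDS || !mut %in% AMINO_ACIDS) {
      stop("non-canonical residue letter in token ", sQuote(tok), call. = FALSE)
    }
    if (wt == mut) {
      stop("silent substitution in token ", sQuote(tok), call. = FALSE)
    }
    mutation_event(wt, as.integer(m[3]), mut)
  })
}

#' Format events back into the canonical mutation string
#'
#' Left inverse of [parse_mutation_string()].
#'
#' @param events list of `mutation_event`s.
#' @return character scalar, events joined by `"+"`.
#' @export
format_mutation_events <- function(events) {
  paste(vapply(events, function(e) paste0(e$wt, e$position, e$mut),
               character(1)), collapse = "+")
}

#' Substitution type of an event (position and protein discarded)
#'
#' Substitutions are grouped by wild-type and mutant residue only,
#' regardless of the protein and of the position of the mutated residue:
#' every A-to-S substitution shares one empirical energy distribution.
#' There are 20 x 19 = 380 possible keys.
#'
#' @param e a `mutation_event`, or a wild-type letter when `mut` is given.
#' @param mut optional mutant residue letter (alternative interface).
#' @return character scalar key of the form `"A>S"`.
#' @examples
#' substitution_key(mutation_event("A", 23, "S"))
#' substitution_key("F", "L")
#' @export
substitution_key <- function(e, mut = NULL) {
  if (!is.null(mut)) return(paste0(e, ">", mut))
  paste0(e$wt, ">", e$mut)
}

#' All 380 possible substitution keys
#' @return character vector of length 380.
#' @export
all_substitution_keys <- function() {
  g <- expand.grid(mut = AMINO_ACIDS, wt = AMINO_ACIDS,
                   stringsAsFactors = FALSE)
  g <- g[g$wt != g$mut, ]
  paste0(g$wt, ">", g$mut)
}

# Keys of one record's events ("A>S" or c("A>S", "F>L")).
record_keys <- function(mutation_string) {
  vapply(parse_mutation_string(mutation_string), substitution_key,
         character(1))
}

#' Assemble a mutation dataset
#'
#' @param records data frame with character columns `record_id`, `protein_id`,
#'   `mutation` and numeric `ddg` (kcal/mol).
#' @param kind `"single"`, `"double"` or `"mixed"`; inferred when `NULL`.
#' @param provenance free-text metadata string.
#' @return a `ddg_dataset` object.
#' @export
ddg_dataset <- function(records, kind = NULL, provenance = "") {
  needed <- c("record_id", "protein_id", "mutation", "ddg")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols)) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  records <- as.data.frame(records)[, needed]
  records$record_id <- as.character(records$record_id)
  records$protein_id <- as.character(records$protein_id)
  records$mutation <- as.character(records$mutation)
  records$ddg <- as.numeric(records$ddg)
  if (anyDuplicated(records$record_id)) {
    dup <- records$record_id[duplicated(records$record_id)][1]
    stop("duplicate record_id: ", sQuote(dup), call. = FALSE)
  }
  if (nrow(records) && any(!is.finite(records$ddg))) {
    stop("non-finite ddg value(s)", call. = FALSE)
  }
  n_events <- integer(nrow(records))
  for (i in seq_len(nrow(records))) {
    ev <- parse_mutation_string(records$mutation[i])
    n_events[i] <- length(ev)
    if (n_events[i] == 2L &&
        ev[[1]]$position == ev[[2]]$position) {
      stop("double mutation at identical positions in record ",
           sQuote(records$record_id[i]), call. = FALSE)
    }
    # normalize notation (uppercase, "+" joiner)
    records$mutation[i] <- format_mutation_events(ev)
  }
  inferred <- if (!nrow(records)) "mixed"
              else if (all(n_events == 1L)) "single"
              else if (all(n_events == 2L)) "double"
              else "mixed"
  kind <- kind %||% inferred
  kind <- match.arg(kind, c("single", "double", "mixed"))
  if (kind != "mixed" && nrow(records) && kind != inferred) {
    stop("kind ", sQuote(kind), " inconsistent with records (", inferred, ")",
         call. = FALSE)
  }
  structure(list(records = records, kind = kind, provenance = provenance),
            class = "ddg_dataset")
}

#' @export
print.ddg_dataset <- function(x, ...) {
  cat(sprintf("<ddg_dataset> %d records (%s)\n", nrow(x$records), x$kind))
  if (nzchar(x$provenance)) cat("provenance:", x$provenance, "\n")
  invisible(x)
}

#' Number of records in a dataset
#' @param d a `ddg_dataset`.
#' @export
n_records <- function(d) nrow(d$records)

#' Parsed events for every record
#' @param d a `ddg_dataset`.
#' @return list of lists of `mutation_event`s, named by record_id.
#' @export
dataset_events <- function(d) {
  ev <- lapply(d$records$mutation, parse_mutation_string)
  names(ev) <- d$records$record_id
  ev
}

# Substitution keys per record, as a list of character vectors.
dataset_keys <- function(d) {
  k <- lapply(d$records$mutation, record_keys)
  names(k) <- d$records$record_id
  k
}

infer_sep <- function(path, sep = NULL) {
  if (!is.null(sep)) return(sep)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a mutation dataset from a delimited text file
#'
#' Expects a UTF-8 header row; TSV or CSV is auto-detected from the file
#' extension (`.csv` means comma) and can be overridden with `sep`.
#'
#' @param path file path.
#' @param sep field separator; `NULL` (default) auto-detects by extension.
#' @param columns named character vector mapping the canonical names
#'   `record_id`, `protein_id`, `mutation`, `ddg` to the file's column names.
#' @param strict if `TRUE` (default) any invalid row aborts the read; if
#'   `FALSE` invalid rows are logged with their line number and skipped.
#' @param kind forwarded to [ddg_dataset()].
#' @return a `ddg_dataset`; in lenient mode the attribute `"rejects"` holds a
#'   data frame of skipped rows (line number + reason).
#' @export
read_ddg_dataset <- function(path, sep = NULL,
                             columns = c(record_id = "record_id",
                                         protein_id = "protein_id",
                                         mutation = "mutation",
                                         ddg = "ddg"),
                             strict = TRUE, kind = NULL) {
  sep <- infer_sep(path, sep)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           quote = "", comment.char = "",
                           fileEncoding = "UTF-8")
  canonical <- c("record_id", "protein_id", "mutation", "ddg")
  columns <- columns[canonical]
  absent <- columns[!columns %in% names(raw)]
  if (length(absent)) {
    stop("missing column(s) in ", path, ": ",
         paste(sQuote(absent), collapse = ", "), call. = FALSE)
  }
  df <- data.frame(record_id = raw[[columns[["record_id"]]]],
                   protein_id = raw[[columns[["protein_id"]]]],
                   mutation = raw[[columns[["mutation"]]]],
                   ddg_raw = raw[[columns[["ddg"]]]],
                   stringsAsFactors = FALSE)
  keep <- rep(TRUE, nrow(df))
  reasons <- character(nrow(df))
  ddg <- suppressWarnings(as.numeric(df$ddg_raw))
  for (i in seq_len(nrow(df))) {
    reason <- NULL
    if (!is.finite(ddg[i])) {
      reason <- paste0("unparseable ddg ", sQuote(df$ddg_raw[i]))
    } else {
      parsed <- tryCatch(parse_mutation_string(df$mutation[i]),
                         error = function(e) conditionMessage(e))
      if (is.character(parsed)) {
        reason <- parsed
      } else if (length(parsed) == 2L &&
                 parsed[[1]]$position == parsed[[2]]$position) {
        reason <- "double mutation at identical positions"
      }
    }
    if (!is.null(reason)) {
      if (strict) {
        stop("line ", i + 1L, " of ", path, ": ", reason, call. = FALSE)
      }
      keep[i] <- FALSE
      reasons[i] <- reason
      ddg_log("skipping line ", i + 1L, ": ", reason, level = "WARN")
    }
  }
  rejects <- data.frame(line = which(!keep) + 1L,
                        record_id = df$record_id[!keep],
                        reason = reasons[!keep],
                        stringsAsFactors = FALSE)
  ok <- df[keep, , drop = FALSE]
  d <- ddg_dataset(data.frame(record_id = ok$record_id,
                              protein_id = ok$protein_id,
                              mutation = ok$mutation,
                              ddg = ddg[keep],
                              stringsAsFactors = FALSE),
                   kind = kind, provenance = path)
  attr(d, "rejects") <- rejects
  d
}

#' Write a mutation dataset to a delimited text file
#'
#' `read_ddg_dataset(write_ddg_dataset(d, path))` reproduces `d` exactly;
#' ddG values are printed with enough digits to round-trip.
#'
#' @param d a `ddg_dataset`.
#' @param path output path; extension selects TSV/CSV unless `sep` is given.
#' @param sep field separator override.
#' @return `path`, invisibly.
#' @export
write_ddg_dataset <- function(d, path, sep = NULL) {
  stopifnot(inherits(d, "ddg_dataset"))
  sep <- infer_sep(path, sep)
  out <- d$records
  out$ddg <- format_ddg(out$ddg)
  utils::write.table(out, path, sep = sep, quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Drop records with |ddG| at or below a neutrality threshold
#'
#' Some published comparisons exclude near-neutral mutations
#' (|ddG| <= 0.5 kcal/mol); this optional filter mirrors that convention.
#'
#' @param d a `ddg_dataset`.
#' @param threshold kcal/mol, default 0.5.
#' @return filtered `ddg_dataset`.
#' @export
exclude_neutral <- function(d, threshold = 0.5) {
  keep <- abs(d$records$ddg) > threshold
  ddg_dataset(d$records[keep, , drop = FALSE], kind = NULL,
              provenance = d$provenance)
}
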