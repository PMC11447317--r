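# CDS input/output: GenBank flat files, multi-FASTA, and the quality filter
# applied before any codon-usage statistic is computed.
#
# A CDS collection is a tibble with columns gene_name, species_id, sequence,
# source_location (one row per coding sequence, plain upper-case ACGT string).

cds_tibble <- function(gene_name = character(), species_id = character(),
                       sequence = character(), source_location = character()) {
  tibble::tibble(
    gene_name = as.character(gene_name),
    species_id = as.character(species_id),
    sequence = toupper(as.character(sequence)),
    source_location = as.character(source_location)
  )
}

#' Read a collection of coding sequences
#'
#' Reads CDS nucleotide sequences either from annotated GenBank flat files
#' (each CDS feature extracted with its coordinates, compound `join()`
#' locations spliced in order and minus-strand features reverse-complemented)
#' or from multi-FASTA files in which each record is one CDS.
#'
#' Gene names come from the `/gene` qualifier (falling back to `/locus_tag`)
#' for GenBank input, and from the first whitespace-delimited token of the
#' header for FASTA input. A FASTA token of the form `species|gene` (the
#' format [write_cds_fasta()] emits) is split back into its two parts.
#'
#' @param paths Character vector of file paths.
#' @param format `"genbank"` or `"fasta"`.
#' @param species_id Species label to attach to every record; defaults to the
#'   GenBank LOCUS name (GenBank input) or the file name without extension
#'   (FASTA input without `species|gene` headers).
#' @return A CDS tibble (columns `gene_name`, `species_id`, `sequence`,
#'   `source_location`). CDS features whose sequence could not be extracted
#'   are recorded in the `extraction_failures` attribute rather than raising
#'   an error.
#' @export
read_cds_collection <- function(paths, format = c("genbank", "fasta"),
                                species_id = NULL) {
  format <- match.arg(format)
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stop("input file(s) not found: ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  parts <- lapply(paths, function(p) {
    if (format == "genbank") .read_genbank_cds(p, species_id) else {
      .read_fasta_cds(p, species_id)
    }
  })
  out <- dplyr::bind_rows(lapply(parts, function(x) x$records))
  attr(out, "extraction_failures") <-
    dplyr::bind_rows(lapply(parts, function(x) x$failures))
  out
}

.read_fasta_cds <- function(path, species_id) {
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0L) {
    return(list(records = cds_tibble(), failures = NULL))
  }
  token <- vapply(
    strsplit(names(set), "[ \t]+"), `[[`, character(1), 1L
  )
  has_sp <- grepl("|", token, fixed = TRUE)
  sp <- ifelse(
    has_sp, sub("\\|.*$", "", token),
    species_id %||% sub("\\.[^.]*$", "", basename(path))
  )
  gene <- ifelse(has_sp, sub("^[^|]*\\|", "", token), token)
  if (!is.null(species_id)) sp <- rep(species_id, length(set))
  list(
    records = cds_tibble(
      gene_name = gene, species_id = sp,
      sequence = as.character(set),
      source_location = paste0(basename(path), ":", seq_along(set))
    ),
    failures = NULL
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- GenBank flat-file CDS extraction ---------------------------------------
# Handles LOCUS/FEATURES/ORIGIN structure, CDS feature locations of the forms
#   a..b    join(a..b,c..d)    complement(a..b)    complement(join(...))
#   join(complement(...), ...)    order(...)
# with < / > partial markers stripped. Coordinates are 1-based inclusive.

.read_genbank_cds <- function(path, species_id) {
  lines <- readLines(path, warn = FALSE)
  locus_rows <- grep("^LOCUS", lines)
  if (!length(locus_rows)) {
    stop("not a GenBank flat file (no LOCUS line): ", path, call. = FALSE)
  }
  ends <- c(locus_rows[-1] - 1L, length(lines))
  recs <- vector("list", length(locus_rows))
  fails <- vector("list", length(locus_rows))
  for (i in seq_along(locus_rows)) {
    chunk <- lines[locus_rows[i]:ends[i]]
    one <- .parse_genbank_record(chunk, path, species_id)
    recs[[i]] <- one$records
    fails[[i]] <- one$failures
  }
  list(
    records = dplyr::bind_rows(recs),
    failures = dplyr::bind_rows(fails)
  )
}

.parse_genbank_record <- function(lines, path, species_id) {
  locus <- strsplit(trimws(sub("^LOCUS", "", lines[1])), "[ \t]+")[[1]][1]
  sp <- species_id %||% locus
  feat_start <- grep("^FEATURES", lines)
  orig_start <- grep("^ORIGIN", lines)
  if (length(feat_start) != 1L || length(orig_start) != 1L) {
    stop(
      "cannot locate FEATURES/ORIGIN sections in ", path,
      " (record ", locus, ")",
      call. = FALSE
    )
  }
  term <- grep("^//", lines)
  term <- if (length(term)) term[1] else length(lines) + 1L
  seq_lines <- lines[(orig_start + 1L):(term - 1L)]
  genome <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))

  flines <- lines[(feat_start + 1L):(orig_start - 1L)]
  # A new feature starts with a key in columns 6-20; continuations are
  # indented further.
  key_rows <- grep("^ {5}[A-Za-z]", flines)
  records <- list()
  failures <- list()
  for (k in seq_along(key_rows)) {
    first <- key_rows[k]
    last <- if (k < length(key_rows)) key_rows[k + 1] - 1L else length(flines)
    key <- strsplit(trimws(flines[first]), "[ \t]+")[[1]][1]
    if (key != "CDS") next
    block <- flines[first:last]
    # location = feature-line remainder plus continuation lines up to the
    # first qualifier
    qual_rows <- grep("^ +/", block)
    loc_end <- if (length(qual_rows)) qual_rows[1] - 1L else length(block)
    loc <- paste(c(
      sub("^ {5}CDS\\s+", "", block[1]),
      trimws(block[seq_len(loc_end)[-1]])
    ), collapse = "")
    gene <- .gb_qualifier(block, "gene") %||%
      .gb_qualifier(block, "locus_tag") %||% paste0("CDS_", k)
    res <- tryCatch(
      .extract_location(genome, loc),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      failures[[length(failures) + 1L]] <- tibble::tibble(
        gene_name = gene, species_id = sp,
        location = loc, reason = conditionMessage(res)
      )
    } else {
      records[[length(records) + 1L]] <- cds_tibble(
        gene_name = gene, species_id = sp, sequence = res,
        source_location = paste0(locus, ":", loc)
      )
    }
  }
  list(
    records = dplyr::bind_rows(records),
    failures = if (length(failures)) dplyr::bind_rows(failures) else NULL
  )
}

.gb_qualifier <- function(block, name) {
  pat <- paste0("^ +/", name, "=\"?([^\"]*)\"?\\s*$")
  hit <- grep(pat, block, value = TRUE)
  if (!length(hit)) {
    return(NULL)
  }
  sub(pat, "\\1", hit[1])
}

.extract_location <- function(genome, loc) {
  loc <- gsub("[<> ]", "", loc)
  .eval_loc <- function(expr) {
    if (grepl("^complement\\(", expr)) {
      inner <- sub("^complement\\((.*)\\)$", "\\1", expr)
      return(.revcomp(.eval_loc(inner)))
    }
    if (grepl("^(join|order)\\(", expr)) {
      inner <- sub("^(join|order)\\((.*)\\)$", "\\2", expr)
      parts <- .split_top_level(inner)
      return(paste(vapply(parts, .eval_loc, character(1)), collapse = ""))
    }
    if (grepl("^[0-9]+\\.\\.[0-9]+$", expr)) {
      ab <- as.integer(strsplit(expr, "..", fixed = TRUE)[[1]])
      if (ab[2] > nchar(genome) || ab[1] < 1L || ab[1] > ab[2]) {
        stop("span ", expr, " outside sequence", call. = FALSE)
      }
      return(substr(genome, ab[1], ab[2]))
    }
    if (grepl("^[0-9]+$", expr)) {
      p <- as.integer(expr)
      if (p < 1L || p > nchar(genome)) {
        stop("position ", expr, " outside sequence", call. = FALSE)
      }
      return(substr(genome, p, p))
    }
    stop("unparseable location component: ", expr, call. = FALSE)
  }
  .eval_loc(loc)
}

.split_top_level <- function(s) {
  depth <- 0L
  cut <- integer()
  chars <- strsplit(s, "")[[1]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") depth <- depth - 1L
    if (chars[i] == "," && depth == 0L) cut <- c(cut, i)
  }
  starts <- c(1L, cut + 1L)
  ends <- c(cut - 1L, length(chars))
  mapply(function(a, b) paste(chars[a:b], collapse = ""), starts, ends)
}

.revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# --- filtering --------------------------------------------------------------

FILTER_RULES <- c(
  "DUPLICATE", "NOT_TRIPLET", "TOO_SHORT", "BAD_BASE",
  "BAD_START", "BAD_STOP", "INTERNAL_STOP"
)

#' Filter coding sequences for codon-usage analysis
#'
#' Applies the standard CDS quality screen used before codon-usage-bias
#' statistics: duplicate gene copies (e.g. from the plastome inverted repeat)
#' are dropped, and every retained CDS must be codon-aligned, at least
#' `min_length` nt long, strictly ACGT, start with ATG, end with a stop codon
#' (TAA/TAG/TGA) and contain no internal stop.
#'
#' Rules are tested in a fixed order and each rejected CDS is reported under
#' its first failing rule: DUPLICATE, NOT_TRIPLET, TOO_SHORT, BAD_BASE,
#' BAD_START, BAD_STOP, INTERNAL_STOP. Duplicate removal is by gene name
#' (case-insensitive, first occurrence kept, per species); with
#' `dedup_sequence = TRUE` an exact-sequence second pass also removes
#' identical copies under different names.
#'
#' @param records A CDS tibble as returned by [read_cds_collection()].
#' @param min_length Minimum retained length in nt. The length test is
#'   `>= min_length` by default; `strict_greater = TRUE` switches it to `>`.
#' @param strict_greater Use a strict `>` length comparison.
#' @param dedup_gene_name Drop later records sharing a gene name (default TRUE).
#' @param dedup_sequence Also drop later records with an identical sequence
#'   within a species (default TRUE).
#' @return A list with `records` (the retained CDS tibble, input order
#'   preserved) and `report`, itself a list with `n_input`, `n_retained` and a
#'   `rejections` tibble (gene_name, species_id, rule).
#' @export
filter_cds <- function(records, min_length = 300, strict_greater = FALSE,
                       dedup_gene_name = TRUE, dedup_sequence = TRUE) {
  stopifnot(is.data.frame(records))
  n <- nrow(records)
  rule <- rep(NA_character_, n)
  if (n) {
    key_gene <- paste(records$species_id, tolower(records$gene_name))
    key_seq <- paste(records$species_id, records$sequence)
    dup <- if (dedup_gene_name) duplicated(key_gene) else rep(FALSE, n)
    if (dedup_sequence) dup <- dup | duplicated(key_seq)
    len <- nchar(records$sequence)
    first3 <- substr(records$sequence, 1L, 3L)
    ok_len <- if (strict_greater) len > min_length else len >= min_length
    for (i in seq_len(n)) {
      s <- records$sequence[i]
      rule[i] <- if (dup[i]) {
        "DUPLICATE"
      } else if (len[i] %% 3L != 0L) {
        "NOT_TRIPLET"
      } else if (!ok_len[i]) {
        "TOO_SHORT"
      } else if (grepl("[^ACGT]", s)) {
        "BAD_BASE"
      } else if (first3[i] != "ATG") {
        "BAD_START"
      } else if (!substr(s, len[i] - 2L, len[i]) %in% STOP_CODONS) {
        "BAD_STOP"
      } else if (.has_internal_stop(s)) {
        "INTERNAL_STOP"
      } else {
        NA_character_
      }
    }
  }
  keep <- is.na(rule)
  rejections <- tibble::tibble(
    gene_name = records$gene_name[!keep],
    species_id = records$species_id[!keep],
    rule = rule[!keep]
  )
  list(
    records = records[keep, , drop = FALSE],
    report = list(
      n_input = n,
      n_retained = sum(keep),
      rejections = rejections
    )
  )
}

.has_internal_stop <- function(s) {
  n <- nchar(s)
  if (n < 6L) {
    return(FALSE)
  }
  body <- substr(s, 1L, n - 3L)
  codons <- substring(body, seq(1L, nchar(body) - 2L, 3L),
                      seq(3L, nchar(body), 3L))
  any(codons %in% STOP_CODONS)
}

#' Write a CDS collection as multi-FASTA
#'
#' Headers take the form `species_id|gene_name`, which
#' [read_cds_collection()] parses back, making write-then-read a round trip.
#'
#' @param records A CDS tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cds_fasta <- function(records, path) {
  if (nrow(records) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  set <- Biostrings::DNAStringSet(records$sequence)
  names(set) <- paste0(records$species_id, "|", records$gene_name)
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Write a filtering report as a tab-separated table
#'
#' @param report The `report` element returned by [filter_cds()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_filter_report <- function(report, path) {
  tab <- report$rejections
  tab$decision <- "rejected"
  tab <- tab[, c("gene_name", "species_id", "decision", "rule")]
  write.table(tab, path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
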