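# Table readers/writers, lightweight SMILES grammar validation, the
# embedding cache, and run manifests. Tables are UTF-8 CSV (RFC 4180
# quoting, since disease definitions contain commas) with a TSV dialect
# selected by file extension or the `sep` argument.

table_sep <- function(path, sep = NULL) {
  if (!is.null(sep)) return(sep)
  if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
}

read_table_checked <- function(path, required, sep = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = table_sep(path, sep),
                          quote = "\"", stringsAsFactors = FALSE,
                          comment.char = "", fill = FALSE,
                          colClasses = "character", encoding = "UTF-8")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop(sprintf("%s: missing required column(s): %s", basename(path),
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  df
}

#' Check a SMILES string against a minimal grammar
#'
#' Accepts organic-subset atom symbols, bonds, branches and ring-bond
#' digits; requires balanced parentheses and paired ring-closure digits.
#' This is a syntax check, not a chemistry validation.
#'
#' @param smiles character scalar.
#' @return `TRUE` if the string passes.
#' @export
smiles_ok <- function(smiles) {
  if (is.na(smiles) || !nzchar(smiles)) return(FALSE)
  chars <- strsplit(smiles, "", fixed = TRUE)[[1]]
  allowed <- c(LETTERS, letters, as.character(0:9),
               "(", ")", "[", "]", "=", "#", "@", "+", "-", "/", "\\", "%", ".")
  if (!all(chars %in% allowed)) return(FALSE)
  depth <- 0L
  for (ch in chars) {
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L) return(FALSE)
    }
  }
  if (depth != 0L) return(FALSE)
  digits <- chars[chars %in% as.character(0:9)]
  all(table(digits) %% 2 == 0)
}

#' Read and validate drug and disease tables
#'
#' Drug table: header `drug_id,smiles`; disease table: header
#' `disease_id,name,synonymous,definition` (empty synonym/definition cells
#' allowed). Duplicate ids and empty SMILES/names are rejected with row
#' numbers.
#'
#' @param drug_path,disease_path table paths (CSV, or TSV by extension).
#' @param validate_smiles also run the [smiles_ok()] grammar check.
#' @param sep optional field separator override.
#' @return list with `drugs` and `diseases` data.frames.
#' @export
read_entities <- function(drug_path, disease_path, validate_smiles = FALSE,
                          sep = NULL) {
  drugs <- read_table_checked(drug_path, c("drug_id", "smiles"), sep)
  dup <- duplicated(drugs$drug_id)
  if (any(dup)) {
    stop("duplicate drug_id at row(s): ", paste(which(dup), collapse = ", "),
         call. = FALSE)
  }
  empty <- which(is.na(drugs$smiles) | !nzchar(drugs$smiles))
  if (length(empty) > 0L) {
    stop("empty SMILES at row(s): ", paste(empty, collapse = ", "), call. = FALSE)
  }
  if (validate_smiles) {
    bad <- which(!vapply(drugs$smiles, smiles_ok, logical(1)))
    if (length(bad) > 0L) {
      stop("SMILES failed the grammar check at row(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  diseases <- read_table_checked(disease_path,
                                 c("disease_id", "name", "synonymous", "definition"), sep)
  dup <- duplicated(diseases$disease_id)
  if (any(dup)) {
    stop("duplicate disease_id at row(s): ", paste(which(dup), collapse = ", "),
         call. = FALSE)
  }
  noname <- which(is.na(diseases$name) | !nzchar(diseases$name))
  if (length(noname) > 0L) {
    stop("empty disease name at row(s): ", paste(noname, collapse = ", "),
         call. = FALSE)
  }
  diseases$synonymous[is.na(diseases$synonymous)] <- ""
  diseases$definition[is.na(diseases$definition)] <- ""
  message(sprintf("read %d drugs, %d diseases", nrow(drugs), nrow(diseases)))
  list(drugs = drugs, diseases = diseases)
}

#' Read the positive association table
#'
#' Pairs referencing unknown entities are dropped with a warning listing the
#' offenders (or rejected outright with `strict = TRUE`); duplicate pairs
#' are collapsed with a warning count.
#'
#' @param path association table with header `drug_id,disease_id`.
#' @param drugs,diseases loaded entity tables.
#' @param strict error (instead of warn-and-drop) on unknown ids.
#' @param sep optional field separator override.
#' @return data.frame of unique known positive pairs.
#' @export
read_associations <- function(path, drugs, diseases, strict = FALSE, sep = NULL) {
  pairs <- read_table_checked(path, c("drug_id", "disease_id"), sep)
  unknown <- !(pairs$drug_id %in% drugs$drug_id) |
    !(pairs$disease_id %in% diseases$disease_id)
  if (any(unknown)) {
    offenders <- paste(pairs$drug_id[unknown], pairs$disease_id[unknown], sep = "/")
    msg <- sprintf("%d pair(s) reference unknown entities: %s", sum(unknown),
                   paste(utils::head(offenders, 10L), collapse = ", "))
    if (strict) stop(msg, call. = FALSE)
    warning(msg, call. = FALSE)
    pairs <- pairs[!unknown, , drop = FALSE]
  }
  dup <- duplicated(paste(pairs$drug_id, pairs$disease_id, sep = "\r"))
  if (any(dup)) {
    warning(sprintf("%d duplicated pair(s) collapsed", sum(dup)), call. = FALSE)
    pairs <- pairs[!dup, , drop = FALSE]
  }
  if (nrow(pairs) == 0L) warning("association table is empty", call. = FALSE)
  rownames(pairs) <- NULL
  pairs
}

#' Write / read an embedding cache
#'
#' Embeddings are stored as a flat little-endian double array
#' (`embeddings.bin`) beside a JSON index mapping each entity id to its
#' offset and shape, with a versioned header. Write-once: refuses to
#' overwrite an existing cache.
#'
#' @param mats named list of numeric matrices or vectors (one per entity).
#' @param dir cache directory.
#' @param adapter_id string recorded in the index for invalidation checks.
#' @return `dir`, invisibly.
#' @export
write_embedding_cache <- function(mats, dir, adapter_id = "unknown") {
  if (file.exists(file.path(dir, "index.json"))) {
    stop("embedding cache already exists (write-once): ", dir, call. = FALSE)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  con <- file(file.path(dir, "embeddings.bin"), "wb")
  on.exit(close(con))
  index <- list()
  offset <- 0
  for (id in names(mats)) {
    m <- mats[[id]]
    shape <- if (is.matrix(m)) dim(m) else c(1L, length(m))
    vals <- as.numeric(if (is.matrix(m)) t(m) else m)  # row-major
    writeBin(vals, con, size = 8L, endian = "little")
    index[[id]] <- list(offset = offset, shape = shape)
    offset <- offset + length(vals)
  }
  jsonlite::write_json(list(format = "ddapred-embedding-cache", version = 1L,
                            adapter_id = adapter_id, entries = index),
                       file.path(dir, "index.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_embedding_cache
#' @param ids entity ids to load (default: all).
#' @export
read_embedding_cache <- function(dir, ids = NULL) {
  idx_path <- file.path(dir, "index.json")
  if (!file.exists(idx_path)) stop("no embedding cache at ", dir, call. = FALSE)
  idx <- jsonlite::read_json(idx_path)
  if (!identical(idx$format, "ddapred-embedding-cache")) {
    stop("unrecognized cache format", call. = FALSE)
  }
  entries <- idx$entries
  if (is.null(ids)) ids <- names(entries)
  con <- file(file.path(dir, "embeddings.bin"), "rb")
  on.exit(close(con))
  out <- list()
  for (id in ids) {
    e <- entries[[id]]
    if (is.null(e)) stop("entity not in cache: ", id, call. = FALSE)
    shape <- unlist(e$shape)
    seek(con, where = e$offset * 8, origin = "start")
    vals <- readBin(con, "numeric", n = prod(shape), size = 8L, endian = "little")
    out[[id]] <- matrix(vals, shape[1L], shape[2L], byrow = TRUE)
  }
  out
}

#' Write a run manifest
#'
#' Records the package version, global seed and a config echo beside run
#' outputs, sufficient to reproduce the run bit-for-bit on the same numeric
#' backend. Deliberately excludes timestamps so repeated runs are identical.
#'
#' @param dir output directory.
#' @param seed global seed of the run.
#' @param config list of configuration values to echo.
#' @param inputs optional named list of input paths.
#' @return the manifest path, invisibly.
#' @export
write_manifest <- function(dir, seed, config = list(), inputs = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(
    list(tool = "ddapred",
         version = as.character(utils::packageVersion("ddapred")),
         seed = seed, config = config, inputs = inputs),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
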