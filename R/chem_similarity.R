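## Compound structures, fingerprints, Tanimoto similarity.
##
## Structure handling (SMILES parsing, canonicalization, molecular weight)
## goes through OpenBabel via ChemmineOB; fingerprints are ChemmineR 2048-bit
## atom-pair fingerprints. Only the Tanimoto arithmetic and the edge-list
## thresholding are implemented here.

#' Create a compound set
#'
#' A `compound_set` is the container used throughout the package: a table of
#' compound identifiers with (optionally) canonical SMILES, plus an optional
#' fingerprint matrix with one row per compound.
#'
#' @param info data.frame with columns `id`, `name`, `smiles` (NA allowed in
#'   synthetic mode).
#' @param fingerprints integer 0/1 matrix, rows named by compound id, or NULL.
#' @return An object of class `compound_set`.
#' @export
compound_set <- function(info, fingerprints = NULL) {
  stopifnot(is.data.frame(info), all(c("id", "name", "smiles") %in% names(info)))
  info$id <- as.character(info$id)
  if (anyDuplicated(info$id)) stop_bn("compound ids must be unique")
  if (!is.null(fingerprints)) {
    fingerprints <- as.matrix(fingerprints)
    storage.mode(fingerprints) <- "integer"
    if (is.null(rownames(fingerprints))) rownames(fingerprints) <- info$id
    if (!identical(rownames(fingerprints), info$id))
      stop_bn("fingerprint rows must match compound ids, in order")
  }
  structure(list(info = info, fingerprints = fingerprints),
            class = "compound_set")
}

#' @export
print.compound_set <- function(x, ...) {
  cat("<compound_set> ", nrow(x$info), " compounds; fingerprints: ",
      if (is.null(x$fingerprints)) "none"
      else paste0(ncol(x$fingerprints), " bits"), "\n", sep = "")
  invisible(x)
}

#' @export
length.compound_set <- function(x) nrow(x$info)

## ---- OpenBabel helpers -----------------------------------------------------

# one record at a time: OpenBabel's SMILES reader aborts the whole stream at
# the first malformed record, so batching would silently drop the remainder.
# Each record echoes "cansmi\tid[ MW]"; an empty result marks invalid input.
ob_convert <- function(smiles, ids, append_mw = FALSE) {
  ids <- as.character(ids)
  if (any(grepl("[[:space:]]", ids))) stop_bn("compound ids must not contain whitespace")
  cf_args <- list("SMI", "CAN", source = NULL)
  if (append_mw) cf_args$options <- data.frame(names = "append", args = "MW")
  rows <- lapply(seq_along(smiles), function(i) {
    cf_args$source <- paste0(smiles[i], " ", ids[i], "\n")
    out <- tryCatch(do.call(ChemmineOB::convertFormat, cf_args),
                    error = function(e) "")
    line <- strsplit(out, "\n", fixed = TRUE)[[1]]
    line <- line[nzchar(line)]
    if (length(line) != 1)
      return(data.frame(id = ids[i], canonical = NA_character_, mw = NA_real_,
                        valid = FALSE, stringsAsFactors = FALSE))
    can <- sub("\t.*$", "", line)
    rest <- sub("^[^\t]*\t", "", line)
    mw <- if (append_mw) as.numeric(sub("^.* ", "", rest)) else NA_real_
    data.frame(id = ids[i], canonical = can, mw = mw, valid = TRUE,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Canonicalize SMILES strings
#'
#' Uses OpenBabel canonical SMILES so that input dialects (aromatic vs.
#' kekulized, atom ordering) do not change downstream fingerprints.
#'
#' @param smiles character vector.
#' @return character vector of canonical SMILES; NA where unparseable.
#' @export
canonical_smiles <- function(smiles) {
  res <- ob_convert(smiles, sprintf("s%06d", seq_along(smiles)))
  res$canonical
}

## ---- parsing ---------------------------------------------------------------

#' Parse compound structures from a SMILES list or SDF file
#'
#' SMILES files carry one `SMILES<TAB>id[<TAB>name]` record per line (spaces
#' also accepted as separators). SDF records take their id from `id_field` in
#' the data block when present, falling back to the molecule title. Records
#' that fail to parse are skipped and reported with their line / record
#' numbers.
#'
#' @param path input file.
#' @param format `"auto"` (by extension), `"smiles"` or `"sdf"`.
#' @param id_field SDF data-block property holding the compound id.
#' @return A [compound_set] with canonical SMILES. The number of skipped
#'   records is attached as attribute `n_skipped`.
#' @export
parse_structures <- function(path, format = c("auto", "smiles", "sdf"),
                             id_field = "ID") {
  format <- match.arg(format)
  if (!file.exists(path)) stop_bn("structure file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.sdf$", path, ignore.case = TRUE)) "sdf" else "smiles"

  if (format == "smiles") {
    lines <- readLines(path, warn = FALSE)
    keep <- which(nzchar(trimws(lines)) & !startsWith(trimws(lines), "#"))
    if (length(keep) == 0) stop_bn("zero valid records in ", path)
    toks <- strsplit(trimws(lines[keep]), "[\t ]+")
    smiles <- vapply(toks, `[`, "", 1)
    ids <- vapply(toks, function(t) if (length(t) >= 2) t[2] else NA_character_, "")
    names <- vapply(toks, function(t) if (length(t) >= 3)
      paste(t[-(1:2)], collapse = " ") else NA_character_, "")
    ids[is.na(ids)] <- sprintf("line%d", keep[is.na(ids)])
    conv <- ob_convert(smiles, ids)
    bad <- which(!conv$valid)
    if (length(bad))
      warning(sprintf("skipped %d unparseable SMILES record(s) at line(s) %s",
                      length(bad), paste(keep[bad], collapse = ", ")))
    ok <- conv$valid
    if (!any(ok)) stop_bn("zero valid records in ", path)
    n_skipped <- sum(!ok)
    info <- data.frame(id = ids[ok],
                       name = ifelse(is.na(names[ok]), ids[ok], names[ok]),
                       smiles = conv$canonical[ok],
                       stringsAsFactors = FALSE)
  } else {
    sdf <- ChemmineR::read.SDFset(path)
    ids <- vapply(seq_along(sdf), function(i) {
      db <- ChemmineR::datablock(sdf[[i]])
      if (id_field %in% names(db) && nzchar(db[[id_field]])) db[[id_field]]
      else ChemmineR::sdfid(sdf[i])
    }, "")
    valid <- ChemmineR::validSDF(sdf)
    if (any(!valid))
      warning(sprintf("skipped %d invalid SDF record(s): %s",
                      sum(!valid), paste(which(!valid), collapse = ", ")))
    if (!any(valid)) stop_bn("zero valid records in ", path)
    sdf <- sdf[valid]
    ids <- ids[valid]
    smi <- as.character(ChemmineR::sdf2smiles(sdf))
    conv <- ob_convert(smi, ids)
    info <- data.frame(id = ids, name = ids, smiles = conv$canonical,
                       stringsAsFactors = FALSE)
    bad <- sum(!conv$valid)
    if (bad) warning(sprintf("%d SDF record(s) could not be canonicalized", bad))
    n_skipped <- sum(!valid) + bad
  }
  out <- compound_set(info)
  attr(out, "n_skipped") <- n_skipped
  out
}

## ---- molecular weight ------------------------------------------------------

#' Compute average molecular weight
#'
#' Average (not monoisotopic) molecular weight in g/mol, including implicit
#' hydrogens, computed by OpenBabel from conventional standard atomic masses
#' and rounded half-up to two decimals — the precision at which suppliers and
#' compound tables print formula weights.
#'
#' @param x a [compound_set] or a character vector of SMILES.
#' @param digits decimals to round to (default 2).
#' @return named numeric vector of molecular weights.
#' @export
compute_molecular_weight <- function(x, digits = 2) {
  if (inherits(x, "compound_set")) {
    smiles <- x$info$smiles
    ids <- x$info$id
  } else {
    smiles <- as.character(x)
    ids <- names(x) %||% sprintf("s%06d", seq_along(smiles))
  }
  if (anyNA(smiles)) stop_bn("missing structures: molecular weight needs SMILES")
  res <- ob_convert(smiles, ids, append_mw = TRUE)
  if (any(!res$valid))
    stop_bn("unparseable structure(s): ", paste(ids[!res$valid], collapse = ", "))
  stats::setNames(round_half_up(res$mw, digits), ids)
}

## ---- fingerprints ----------------------------------------------------------

#' Compute structural fingerprints for a compound set
#'
#' Atom-pair fingerprints (ChemmineR `sdf2ap()` folded to a fixed-length bit
#' vector by `desc2fp()`), computed from canonical SMILES so equivalent input
#' dialects give identical bits. Molecules too small to yield any atom pair
#' (e.g. single heavy atoms) get an all-zero fingerprint with a warning; they
#' can never reach the similarity threshold.
#'
#' @param compounds a [compound_set] with SMILES.
#' @param fp_length fingerprint length in bits: 512, 1024, 2048 or 4096.
#' @param fp_kind fingerprint family; `"atompair"` is the only built-in kind.
#' @return the [compound_set] with its `fingerprints` matrix filled in.
#' @export
compute_fingerprints <- function(compounds, fp_length = 2048,
                                 fp_kind = "atompair") {
  stopifnot(inherits(compounds, "compound_set"))
  if (!identical(fp_kind, "atompair"))
    stop_bn("unknown fingerprint kind: ", fp_kind)
  if (!fp_length %in% c(512, 1024, 2048, 4096))
    stop_bn("fp_length must be one of 512, 1024, 2048, 4096")
  smiles <- compounds$info$smiles
  if (anyNA(smiles))
    stop_bn("missing structures: compounds without SMILES cannot be ",
            "fingerprinted (synthetic mode carries fingerprints directly)")
  ids <- compounds$info$id
  fp <- matrix(0L, nrow = length(ids), ncol = fp_length, dimnames = list(ids, NULL))
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(stats::setNames(smiles, ids)))
  valid <- ChemmineR::validSDF(sdf)
  if (any(valid)) {
    ap <- suppressWarnings(ChemmineR::sdf2ap(sdf[valid]))
    # most-frequent atom-pair descriptor set shipped with ChemmineR; loaded
    # explicitly because desc2fp's own data() lookup needs the caller's env
    fp_env <- new.env()
    utils::data("apfp", package = "ChemmineR", envir = fp_env)
    descnames <- as.character(utils::head(fp_env$apfp$AP, fp_length))
    m <- ChemmineR::desc2fp(ap, descnames = descnames, type = "matrix")
    fp[ids[valid], ] <- as.integer(m)
  }
  empty <- rowSums(fp) == 0
  if (any(empty))
    warning(sprintf("%d compound(s) have empty fingerprints: %s",
                    sum(empty), paste(ids[empty], collapse = ", ")))
  compounds$fingerprints <- fp
  compounds
}

## ---- Tanimoto --------------------------------------------------------------

#' Tanimoto coefficient between two binary fingerprints
#'
#' `Tc = |a AND b| / |a OR b|` over set bits. Two all-zero fingerprints give
#' 0 with a warning: featureless structures must never form similarity edges.
#'
#' @param fa,fb 0/1 vectors of equal length.
#' @return Tanimoto coefficient in \[0, 1\].
#' @export
tanimoto <- function(fa, fb) {
  if (length(fa) != length(fb)) stop_bn("fingerprint length mismatch")
  fa <- as.logical(fa); fb <- as.logical(fb)
  un <- sum(fa | fb)
  if (un == 0) {
    warning("both fingerprints empty; Tanimoto defined as 0")
    return(0)
  }
  sum(fa & fb) / un
}

#' All-pairs Tanimoto matrix
#'
#' Dense n-by-n Tanimoto matrix computed by one cross-product over the 0/1
#' fingerprint matrix; pairs of all-zero fingerprints get 0.
#'
#' @param fingerprints integer 0/1 matrix, rows = compounds.
#' @return symmetric numeric matrix with unit diagonal (0 for empty rows).
#' @export
tanimoto_matrix <- function(fingerprints) {
  m <- as.matrix(fingerprints)
  storage.mode(m) <- "double"
  inter <- tcrossprod(m)
  ones <- rowSums(m)
  un <- outer(ones, ones, "+") - inter
  tc <- ifelse(un > 0, inter / un, 0)
  dimnames(tc) <- list(rownames(m), rownames(m))
  tc
}

#' Threshold pairwise similarities into an edge list
#'
#' Scans all unordered compound pairs and keeps those with Tanimoto at or
#' above `threshold`, each stored once with `a < b` lexicographically.
#'
#' @param compounds a [compound_set] with fingerprints, or a fingerprint
#'   matrix.
#' @param threshold minimum Tanimoto coefficient (default 0.8).
#' @param max_compounds soft cap on n; above it the quadratic scan proceeds
#'   with a warning.
#' @return data.frame with columns `a`, `b`, `tc`.
#' @export
build_similarity_edges <- function(compounds, threshold = 0.8,
                                   max_compounds = 5000) {
  fp <- if (inherits(compounds, "compound_set")) {
    if (is.null(compounds$fingerprints))
      stop_bn("fingerprints not computed; call compute_fingerprints() first")
    compounds$fingerprints
  } else as.matrix(compounds)
  n <- nrow(fp)
  if (n > max_compounds)
    warning(sprintf("similarity scan over %d compounds (%.1fM pairs)",
                    n, n * (n - 1) / 2e6))
  if (n < 2)
    return(data.frame(a = character(), b = character(), tc = numeric()))
  tc <- tanimoto_matrix(fp)
  idx <- which(upper.tri(tc) & tc >= threshold, arr.ind = TRUE)
  ids <- rownames(fp) %||% as.character(seq_len(n))
  out <- data.frame(a = ids[idx[, 1]], b = ids[idx[, 2]],
                    tc = tc[idx], stringsAsFactors = FALSE)
  swap <- out$a > out$b
  tmp <- out$a[swap]; out$a[swap] <- out$b[swap]; out$b[swap] <- tmp
  out[order(out$a, out$b), , drop = FALSE]
}

#' Write a similarity edge list as TSV
#'
#' @param edges data.frame from [build_similarity_edges()].
#' @param path output file; `tc` is printed with 4 decimals.
#' @export
write_edges_tsv <- function(edges, path) {
  out <- data.frame(a = edges$a, b = edges$b, tc = sprintf("%.4f", edges$tc))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
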