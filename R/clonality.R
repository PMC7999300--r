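#' Assemble a samples-by-variants presence matrix
#'
#' Columns are the union of variants over all samples, ordered by
#' (chrom, pos, alt); rows are samples in the order given. Cells hold
#' presence tiers from [call_presence()] (absent/low/mid/high encoded
#' 0/1/2/3); sample/variant pairs with no call are absent. Two calls for one
#' (sample, variant) pair with different depths are rejected as inconsistent.
#'
#' @param samples List of per-sample call sets as returned by
#'   [sample_organoid()] / [sample_bulk()] (elements need `sample_id`,
#'   `role`, `calls`).
#' @param t_low,t_mid,min_alt_reads Presence thresholds, see
#'   [call_presence()].
#' @return Object of class `presence_matrix`: integer matrix (samples x
#'   variants) with attributes `roles` (named by sample) and `thresholds`,
#'   and a `variants` data.frame attribute (chrom, pos, ref, alt).
#' @export
build_presence_matrix <- function(samples, t_low = 0.10, t_mid = 0.20,
                                  min_alt_reads = 3L) {
  if (!length(samples)) stop("need at least one sample")
  ids <- vapply(samples, `[[`, character(1), "sample_id")
  if (anyDuplicated(ids)) stop("duplicate sample ids")
  roles <- setNames(vapply(samples, `[[`, character(1), "role"), ids)
  allcalls <- do.call(rbind, lapply(samples, function(s) {
    df <- s$calls
    if (nrow(df)) df$sample_id <- s$sample_id
    df
  }))
  vkey <- function(df) paste(df$chrom, df$pos, df$alt, sep = ":")
  if (!is.null(allcalls) && nrow(allcalls)) {
    dup <- duplicated(allcalls[c("sample_id", "chrom", "pos", "alt")])
    if (any(dup)) {
      d <- allcalls[c("sample_id", "chrom", "pos", "alt",
                      "alt_depth", "total_depth")]
      if (anyDuplicated(d[c("sample_id", "chrom", "pos", "alt")]) &&
          nrow(unique(d)) != nrow(unique(d[c("sample_id", "chrom",
                                            "pos", "alt")])))
        stop("inconsistent duplicate calls for one (sample, variant) pair")
      allcalls <- allcalls[!dup, , drop = FALSE]
    }
    uv <- unique(allcalls[c("chrom", "pos", "ref", "alt")])
    uv <- uv[order(uv$chrom, uv$pos, uv$alt), , drop = FALSE]
    rownames(uv) <- NULL
  } else {
    uv <- data.frame(chrom = character(), pos = integer(),
                     ref = character(), alt = character())
  }
  mat <- matrix(0L, nrow = length(ids), ncol = nrow(uv),
                dimnames = list(ids, vkey(uv)))
  if (nrow(uv) && nrow(allcalls)) {
    tier <- call_presence(allcalls$alt_depth, allcalls$total_depth,
                          t_low, t_mid, min_alt_reads)
    mat[cbind(match(allcalls$sample_id, ids),
              match(vkey(allcalls), vkey(uv)))] <- as.integer(tier) - 1L
  }
  structure(mat, roles = roles,
            thresholds = list(t_low = t_low, t_mid = t_mid,
                              min_alt_reads = min_alt_reads),
            variants = uv, class = c("presence_matrix", "matrix"))
}

#' Build a presence matrix directly from tier data
#'
#' Convenience constructor for worked examples and fixtures: takes an
#' integer matrix of tiers (0 = absent .. 3 = high) with sample row names
#' and variant column names, plus a role per sample.
#'
#' @param tiers Integer matrix, samples x variants.
#' @param roles Character vector (organoid / primary_biopsy / metastasis /
#'   normal), one per row.
#' @return A `presence_matrix`.
#' @export
presence_matrix <- function(tiers, roles) {
  stopifnot(is.matrix(tiers), length(roles) == nrow(tiers),
            !is.null(rownames(tiers)), !is.null(colnames(tiers)))
  if (anyDuplicated(rownames(tiers))) stop("duplicate sample ids")
  if (anyDuplicated(colnames(tiers))) stop("duplicate variant ids")
  m <- tiers
  mode(m) <- "integer"
  structure(m,
            roles = setNames(as.character(roles), rownames(tiers)),
            thresholds = list(), variants = NULL,
            class = c("presence_matrix", "matrix"))
}

mat_roles <- function(matrix) attr(matrix, "roles")

#' Classify variant sharing across a tumour's organoids
#'
#' Sharing classes are defined over single-cell-derived organoids only:
#' a variant present (any non-absent tier) in all organoids is `trunk`, in
#' exactly one `private`, in more than one but not all `semi_private`.
#' Variants present in no organoid (e.g. biopsy-only) are reported as
#' `unclassified`. With exactly two organoids, trunk and "shared" coincide;
#' the result carries a note to that effect.
#'
#' @param matrix A `presence_matrix`.
#' @param organoids Character vector of organoid sample ids; defaults to all
#'   samples whose role is "organoid". At least 2 required — the
#'   definitions are arities over multiple organoids.
#' @return List with `class` (named factor per variant), `counts` (table of
#'   trunk/semi_private/private/unclassified), and `note`.
#' @export
classify_sharing <- function(matrix, organoids = NULL) {
  roles <- mat_roles(matrix)
  if (is.null(organoids))
    organoids <- names(roles)[roles == "organoid"]
  if (length(organoids) < 2)
    stop("sharing classes are defined over >= 2 organoids ",
         "(trunk = in all, private = in exactly one)")
  sub <- matrix[organoids, , drop = FALSE] > 0
  n_carrier <- colSums(sub)
  cls <- ifelse(n_carrier == 0, "unclassified",
                ifelse(n_carrier == length(organoids), "trunk",
                       ifelse(n_carrier == 1, "private", "semi_private")))
  cls <- factor(cls, levels = c("trunk", "semi_private", "private",
                                "unclassified"))
  names(cls) <- colnames(matrix)
  list(class = cls, counts = table(cls),
       note = if (length(organoids) == 2)
         "with 2 organoids, trunk and shared coincide" else NULL)
}

#' Lower bound on metastasis seeding events
#'
#' Counts the distinct presence profiles among metastasis samples; each
#' distinct profile requires at least one independent seeding event.
#'
#' @param matrix A `presence_matrix`.
#' @param metastases Metastasis sample ids; defaults to samples with role
#'   "metastasis".
#' @return Integer: number of unique metastasis presence patterns (0 if no
#'   metastasis samples).
#' @export
count_seeding_events <- function(matrix, metastases = NULL) {
  roles <- mat_roles(matrix)
  if (is.null(metastases))
    metastases <- names(roles)[roles == "metastasis"]
  if (!length(metastases)) return(0L)
  sub <- matrix[metastases, , drop = FALSE] > 0
  nrow(unique(sub))
}

#' Write / read a presence matrix as TSV plus a JSON sidecar of roles
#' @param matrix A `presence_matrix`.
#' @param path TSV path; the sidecar is written to `<path>.json`.
#' @export
write_presence_matrix <- function(matrix, path) {
  df <- as.data.frame(unclass(matrix))
  df <- cbind(sample_id = rownames(matrix), df)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(roles = as.list(mat_roles(matrix)),
                            thresholds = attr(matrix, "thresholds")),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_presence_matrix
#' @export
read_presence_matrix <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "integer"
  rownames(m) <- df$sample_id
  structure(m, roles = unlist(side$roles),
            thresholds = as.list(side$thresholds), variants = NULL,
            class = c("presence_matrix", "matrix"))
}
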