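#' Fixed reference mutational profiles
#'
#' Three unit-sum 96-class profiles constructed from verbal signature
#' definitions rather than downloaded catalogues, so the package tests run
#' offline: `sig1_like` places 90% of its mass uniformly on the four NpCpG
#' C>T classes (deamination of methylated cytosine), `sig17_like` places 80%
#' on CpTpT-context T>G and T>C, and `uniform` is flat. Profiles can be
#' overridden by supplying any named list of non-negative unit-sum
#' 96-vectors wherever profiles are accepted; a JSON copy ships in
#' `inst/extdata/reference_profiles.json`.
#'
#' @param path Optional JSON file of profiles (named lists of 96 values in
#'   [context_classes()] order).
#' @return Named list of numeric vectors of length 96 (named by class).
#' @export
reference_profiles <- function(path = NULL) {
  cls <- context_classes()
  if (!is.null(path)) {
    raw <- jsonlite::read_json(path, simplifyVector = TRUE)
    return(lapply(raw, function(v) setNames(as.numeric(v), cls)))
  }
  sig1 <- setNames(rep(0.1 / 92, 96), cls)
  cpg <- cls[grepl("^\\w\\[C>T\\]G$", cls)]
  sig1[cpg] <- 0.9 / length(cpg)
  sig17 <- setNames(rep(0.2 / 94, 96), cls)
  ctt <- c("C[T>G]T", "C[T>C]T")
  sig17[ctt] <- 0.8 / length(ctt)
  unif <- setNames(rep(1 / 96, 96), cls)
  list(sig1_like = sig1, sig17_like = sig17, uniform = unif)
}

#' 96-context mutation spectrum
#'
#' Counts variants into the 96 pyrimidine-collapsed trinucleotide
#' substitution classes. Purine-reference substitutions map to the reverse
#' complement class. Variants at chromosome ends, lacking a full 3-mer
#' context, are skipped and counted in the `n_skipped` attribute.
#'
#' @param variants data.frame with chrom, pos (0-based), ref, alt.
#' @param genome A `genome_model`.
#' @return Object of class `spectrum96`: named numeric vector of length 96
#'   with attributes `normalized = FALSE` and `n_skipped`.
#' @export
spectrum96 <- function(variants, genome) {
  cls <- context_classes()
  counts <- setNames(numeric(96), cls)
  if (nrow(variants)) {
    ctx <- variant_context(variants, genome)
    gref <- substr(ctx$triplet, 2, 2)
    bad <- which(!is.na(ctx$triplet) & gref != variants$ref)
    if (length(bad))
      stop("ref mismatch with genome at ", variants$chrom[bad[1]], ":",
           variants$pos[bad[1]])
    lab <- collapse_context(ctx$triplet, variants$alt)
    tab <- table(factor(lab[!is.na(lab)], levels = cls))
    counts[] <- as.numeric(tab)
    n_skipped <- sum(is.na(lab))
  } else n_skipped <- 0L
  structure(counts, normalized = FALSE, n_skipped = n_skipped,
            class = "spectrum96")
}

#' Normalise a spectrum by triplet prevalence
#'
#' Divides each class count by the genomic prevalence of its underlying
#' triplet in the chosen territory, then rescales so the total equals the
#' raw total (shape changes, total preserved). This makes spectra comparable
#' across genomes of different composition — e.g. the NpCpG C>T share grows
#' after normalisation in a CpG-depleted genome.
#'
#' @param spec A `spectrum96`.
#' @param census Named 32-vector of triplet counts from [triplet_census()]
#'   for the same territory the variants come from.
#' @return Normalised `spectrum96` (attribute `normalized = TRUE`).
#' @export
normalize_spectrum <- function(spec, census) {
  stopifnot(inherits(spec, "spectrum96"))
  tri <- class_triplet(names(spec))
  missing <- setdiff(unique(tri), names(census))
  if (length(missing)) stop("census lacks triplets: ",
                            paste(missing, collapse = ", "))
  denom <- as.numeric(census[tri])
  zero_bad <- which(denom == 0 & as.numeric(spec) > 0)
  if (length(zero_bad))
    stop("nonzero spectrum count with zero census for triplet ",
         tri[zero_bad[1]])
  out <- as.numeric(spec)
  nz <- denom > 0
  out[nz] <- out[nz] / denom[nz]
  tot <- sum(spec)
  if (sum(out) > 0) out <- out * tot / sum(out)
  structure(setNames(out, names(spec)), normalized = TRUE,
            n_skipped = attr(spec, "n_skipped"), class = "spectrum96")
}

#' Non-negative decomposition of a spectrum against reference profiles
#'
#' Finds non-negative weights minimising the squared error between the
#' unit-normalised spectrum and a weighted mixture of the reference
#' profiles, by the Lawson-Hanson active-set iteration (exact for the small
#' reference sets used here; the residual is zero to machine precision
#' whenever the spectrum lies in the references' cone). Weights are
#' reported rescaled to sum 1.
#'
#' @param spec A `spectrum96` (raw or normalised).
#' @param refs Named list of unit-sum 96-vectors, default
#'   [reference_profiles()].
#' @param tol Convergence tolerance on the objective (default 1e-8).
#' @param max_iter Iteration cap.
#' @return List with `weights` (named, sum 1), `raw_weights`, `residual`
#'   (Euclidean norm of the unexplained part), and `zero_spectrum` flag.
#' @export
fit_signatures <- function(spec, refs = reference_profiles(), tol = 1e-8,
                           max_iter = 50000L) {
  if (!length(refs)) stop("need at least one reference profile")
  y <- as.numeric(spec)
  if (sum(y) <= 0) {
    w <- setNames(rep(0, length(refs)), names(refs))
    return(list(weights = w, raw_weights = w, residual = 0,
                zero_spectrum = TRUE))
  }
  y <- y / sum(y)
  R <- do.call(cbind, lapply(refs, as.numeric))
  G <- crossprod(R)
  b <- as.numeric(crossprod(R, y))
  w <- nnls_active_set(G, b, tol = tol, max_iter = max_iter)
  obj <- function(w) sum((y - R %*% w)^2)
  raw <- setNames(as.numeric(w), names(refs))
  wn <- if (sum(raw) > 0) raw / sum(raw) else raw
  list(weights = wn, raw_weights = raw,
       residual = sqrt(obj(w)), zero_spectrum = FALSE)
}

# Lawson-Hanson non-negative least squares on the normal equations:
# minimise w'Gw - 2b'w subject to w >= 0. Exact for small problems.
nnls_active_set <- function(G, b, tol = 1e-10, max_iter = 1000L) {
  p <- length(b)
  P <- logical(p)
  w <- numeric(p)
  for (it in seq_len(max_iter)) {
    grad <- b - as.numeric(G %*% w)
    cand <- which(!P & grad > tol)
    if (!length(cand)) break
    P[cand[which.max(grad[cand])]] <- TRUE
    repeat {
      s <- numeric(p)
      s[P] <- solve(G[P, P, drop = FALSE], b[P])
      if (all(s[P] > tol)) { w <- s; break }
      neg <- which(P & s <= tol)
      alpha <- min(w[neg] / (w[neg] - s[neg]))
      w <- w + alpha * (s - w)
      P[w <= tol] <- FALSE
      w[!P] <- 0
    }
  }
  w
}

#' Write a spectrum as TSV (class, count, and normalised column if present)
#' @param spec A `spectrum96`.
#' @param path Output file.
#' @export
write_spectrum <- function(spec, path) {
  df <- data.frame(class = names(spec), count = as.numeric(spec))
  df$normalized <- isTRUE(attr(spec, "normalized"))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
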