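#' Construct a validated, topologically ordered pedigree
#'
#' A pedigree records, for each animal, its sire, dam and birth year. The
#' constructor validates the records (unique animals, acyclic parentage),
#' auto-inserts parents that appear only as sire/dam as founders (with a
#' warning), and reorders the rows so that every parent precedes its
#' offspring — the order all downstream recursions (inbreeding, tabular A,
#' Henderson's A-inverse rules) require.
#'
#' Unknown parents are treated as unrelated founders (a single implicit
#' genetic group); unknown-parent groups and metafounders are out of scope.
#'
#' @param df data.frame with columns `animal`, `sire`, `dam`, `birth_year`
#'   (extra columns are ignored). Ids are handled as character strings.
#' @param unknown_code token(s) marking an unknown parent; `NA` always counts
#'   as unknown.
#' @return An object of class `pedigree`: a list with `id` (character, in
#'   topological order), `sire`/`dam` (integer codes into `id`, 0 = unknown),
#'   `birth_year` (integer) and `n`.
#' @export
as_pedigree <- function(df, unknown_code = c("0", ".")) {
  need <- c("animal", "sire", "dam", "birth_year")
  if (!all(need %in% names(df)))
    stop("pedigree needs columns: ", paste(need, collapse = ", "))
  animal <- as.character(df$animal)
  sire <- as.character(df$sire)
  dam <- as.character(df$dam)
  by <- suppressWarnings(as.integer(df$birth_year))
  unk <- function(x) is.na(x) | x %in% unknown_code | x == ""
  sire[unk(sire)] <- NA_character_
  dam[unk(dam)] <- NA_character_
  if (anyNA(animal) | any(unk(animal))) stop("missing animal id")
  if (anyDuplicated(animal))
    stop("duplicate animal rows: ",
         paste(utils::head(animal[duplicated(animal)], 5), collapse = ", "))
  if (any(!is.na(sire) & sire == animal) || any(!is.na(dam) & dam == animal))
    stop("cycle detected: animal is its own parent: ",
         animal[which(animal == sire | animal == dam)[1]])

  # parents referenced but never defined become founders
  ghosts <- setdiff(stats::na.omit(c(sire, dam)), animal)
  if (length(ghosts)) {
    warning(length(ghosts), " parent(s) not listed as animals; ",
            "inserted as founders: ",
            paste(utils::head(ghosts, 5), collapse = ", "),
            if (length(ghosts) > 5) ", ...")
    animal <- c(animal, ghosts)
    sire <- c(sire, rep(NA_character_, length(ghosts)))
    dam <- c(dam, rep(NA_character_, length(ghosts)))
    by <- c(by, rep(NA_integer_, length(ghosts)))
  }
  n <- length(animal)
  si <- match(sire, animal)
  di <- match(dam, animal)

  # generation number by iterated relaxation; failure to converge = cycle
  gen <- rep(NA_integer_, n)
  gen[is.na(si) & is.na(di)] <- 0L
  repeat {
    gs <- ifelse(is.na(si), -1L, gen[si])
    gd <- ifelse(is.na(di), -1L, gen[di])
    new <- is.na(gen) & !is.na(gs) & !is.na(gd)
    if (!any(new)) break
    gen[new] <- pmax(gs[new], gd[new]) + 1L
  }
  if (anyNA(gen)) {
    # every remaining animal sits on or below a cycle; name one on the cycle
    bad <- which(is.na(gen))
    on_cycle <- bad[1]
    seen <- integer(0)
    cur <- on_cycle
    repeat {
      nxt <- c(si[cur], di[cur])
      nxt <- nxt[!is.na(nxt) & is.na(gen[nxt])]
      if (!length(nxt)) break
      if (nxt[1] %in% seen) { on_cycle <- nxt[1]; break }
      seen <- c(seen, cur)
      cur <- nxt[1]
    }
    stop("cycle detected in pedigree involving animal '", animal[on_cycle], "'")
  }
  ord <- order(gen, seq_len(n))
  animal <- animal[ord]; by <- by[ord]
  remap <- match(seq_len(n), ord)        # old code -> new position
  si <- remap[si[ord]]; di <- remap[di[ord]]
  si[is.na(si)] <- 0L; di[is.na(di)] <- 0L
  structure(list(id = animal, sire = si, dam = di,
                 birth_year = by, n = n),
            class = "pedigree")
}

#' Read a pedigree file
#'
#' Reads a whitespace- or comma-delimited text file with columns
#' `animal sire dam birth_year` (a header row with those names is optional)
#' and returns a validated [as_pedigree()] object.
#'
#' @param path file path.
#' @param unknown_code token(s) marking unknown parents (default `"0"` or `"."`).
#' @return A `pedigree` object.
#' @export
read_pedigree <- function(path, unknown_code = c("0", ".")) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  df <- utils::read.table(path, sep = sep, header = FALSE,
                          colClasses = "character", strip.white = TRUE)
  if (ncol(df) < 4) stop("expected 4 columns: animal sire dam birth_year")
  if (tolower(df[1, 1]) == "animal") df <- df[-1, , drop = FALSE]
  names(df)[1:4] <- c("animal", "sire", "dam", "birth_year")
  as_pedigree(df, unknown_code = unknown_code)
}

#' @export
print.pedigree <- function(x, ...) {
  nf <- sum(x$sire == 0 & x$dam == 0)
  cat("Pedigree:", x$n, "animals (", nf, "founders )\n")
  if (!all(is.na(x$birth_year)))
    cat("  birth years:", min(x$birth_year, na.rm = TRUE), "-",
        max(x$birth_year, na.rm = TRUE), "\n")
  invisible(x)
}

#' Write a pedigree to a delimited text file
#'
#' @param ped a `pedigree`.
#' @param path output path (CSV with header `animal,sire,dam,birth_year`;
#'   unknown parents written as `0`).
#' @export
write_pedigree <- function(ped, path) {
  code_to_id <- function(k) {
    out <- rep("0", ped$n)
    out[k > 0] <- ped$id[k[k > 0]]
    out
  }
  sire <- code_to_id(ped$sire)
  dam <- code_to_id(ped$dam)
  by <- ifelse(is.na(ped$birth_year), "0", as.character(ped$birth_year))
  writeLines(c("animal,sire,dam,birth_year",
               paste(ped$id, sire, dam, by, sep = ",")), path)
  invisible(path)
}

#' Inbreeding coefficients
#'
#' Per-animal inbreeding coefficients f by the Meuwissen–Luo recursion
#' (tracing each animal's ancestor list through the L D L' decomposition of
#' the numerator relationship matrix). Founders and animals with an unknown
#' parent have f = 0; otherwise f equals half the additive relationship
#' between the parents, i.e. `diag(a_matrix(ped)) - 1`.
#'
#' @param ped a `pedigree`.
#' @return named numeric vector of inbreeding coefficients in pedigree order.
#' @export
inbreeding <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  f <- ml_inbreeding_cpp(ped$sire, ped$dam)
  names(f) <- ped$id
  f
}

#' Numerator relationship matrix (tabular method)
#'
#' Dense additive (numerator) relationship matrix A by the tabular recursive
#' method, restricted to the requested animals. The recursion always runs
#' over the whole pedigree so that relationships through ancestors outside
#' the subset are carried; only the returned rows/columns are restricted.
#'
#' @param ped a `pedigree`.
#' @param subset character vector of animal ids (default: all).
#' @return symmetric matrix with `diag = 1 + f`, dimnames = ids.
#' @export
a_matrix <- function(ped, subset = ped$id) {
  stopifnot(inherits(ped, "pedigree"))
  idx <- match(subset, ped$id)
  if (anyNA(idx))
    stop("ids not in pedigree: ",
         paste(utils::head(subset[is.na(idx)], 5), collapse = ", "))
  if (ped$n > 20000L)
    stop("dense tabular A not supported beyond 20000 animals")
  A <- tabular_a_cpp(ped$sire, ped$dam)
  A <- A[idx, idx, drop = FALSE]
  dimnames(A) <- list(subset, subset)
  A
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Henderson's rules with inbreeding: each animal contributes
#' `b = 1/m` to the coefficient pattern, where the Mendelian-sampling
#' variance is `m = 0.5 - 0.25 (f_s + f_d)` with `f = -1` substituted for an
#' unknown parent (which reproduces the 3/4 and 1 variances of the
#' one-/zero-known-parent cases).
#'
#' @param ped a `pedigree`.
#' @return sparse symmetric `Matrix::dgCMatrix` with dimnames = ids.
#' @export
a_inverse <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  n <- ped$n
  f <- ml_inbreeding_cpp(ped$sire, ped$dam)
  s <- ped$sire; d <- ped$dam
  fs <- ifelse(s > 0, f[pmax(s, 1)], -1)
  fd <- ifelse(d > 0, f[pmax(d, 1)], -1)
  b <- 1 / (0.5 - 0.25 * (fs + fd))
  i <- seq_len(n)
  ks <- which(s > 0)
  kd <- which(d > 0)
  kb <- which(s > 0 & d > 0)
  ii <- c(i, ks, s[ks], s[ks], kd, d[kd], d[kd], s[kb], d[kb])
  jj <- c(i, s[ks], ks, s[ks], d[kd], kd, d[kd], d[kb], s[kb])
  xx <- c(b, -b[ks] / 2, -b[ks] / 2, b[ks] / 4,
          -b[kd] / 2, -b[kd] / 2, b[kd] / 4,
          b[kb] / 4, b[kb] / 4)
  M <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                            dimnames = list(ped$id, ped$id))
  methods::as(M, "CsparseMatrix")
}
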