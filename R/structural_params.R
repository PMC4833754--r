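#' E-F distance of a dimer
#'
#' Distance between the Calpha atoms of two marker residues spanning the
#' heme pocket (Leu66 on the E helix and Ile102 by default), computed per
#' subunit; the headline value is the mean over the two subunits.
#'
#' @param structure a two-chain `trxss_structure`
#' @param residues length-2 residue numbers (default `c(66, 102)`)
#' @return list with `per_chain` (named vector, Angstrom) and `mean`
#' @export
ef_distance <- function(structure, residues = c(66, 102)) {
  chains <- sort(unique(structure$chain[structure$type == "ATOM" &
                                          !structure$is_water]))
  chains <- chains[chains != "W"]
  per <- vapply(chains, function(ch) {
    pick <- function(r) {
      i <- which(structure$chain == ch & structure$resno == r &
                   structure$elety == "CA")
      if (length(i) != 1L) {
        stop("missing Calpha for residue ", r, " in chain ", ch)
      }
      coords(structure, i)[1, ]
    }
    sqrt(sum((pick(residues[1]) - pick(residues[2]))^2))
  }, numeric(1))
  list(per_chain = per, mean = mean(per))
}

#' Kabsch least-squares superposition
#'
#' Optimal proper rotation (det = +1) and translation mapping `mobile`
#' onto `reference`, plus the RMSD after superposition. Points must be
#' matched one-to-one.
#'
#' @param mobile,reference n x 3 coordinate matrices, n >= 3
#' @return list with `rotation` (3x3), `translation` (length 3 such that
#'   the superposed mobile set is `mobile %*% t(rotation) + translation`),
#'   `rmsd`, and `degenerate` flag set for (near-)collinear point sets
#' @export
kabsch_superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile)
  reference <- as.matrix(reference)
  stopifnot(ncol(mobile) == 3, all(dim(mobile) == dim(reference)))
  if (nrow(mobile) < 3L) stop("need at least 3 points")
  cm <- colMeans(mobile)
  cr <- colMeans(reference)
  A <- sweep(mobile, 2, cm)
  B <- sweep(reference, 2, cr)
  H <- t(A) %*% B
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  degenerate <- sv$d[2] < 1e-8 * max(sv$d[1], 1e-300)
  fitted <- A %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - B)^2)))
  list(rotation = R, translation = as.numeric(cr - R %*% cm), rmsd = rmsd,
       degenerate = degenerate)
}

# matched Calpha coordinate sets of one chain, ordered by residue number
chain_ca <- function(structure, ch) {
  i <- which(structure$chain == ch & structure$elety == "CA" &
               !structure$is_water)
  i <- i[order(structure$resno[i])]
  coords(structure, i)
}

#' Calpha RMSD between two structures after superposition
#'
#' @param structure,reference matched `trxss_structure`s (same chains,
#'   same Calpha count per chain)
#' @return RMSD in Angstrom
#' @export
ca_rmsd <- function(structure, reference) {
  chains <- intersect(sort(unique(structure$chain)),
                      sort(unique(reference$chain)))
  chains <- chains[chains != "W"]
  A <- do.call(rbind, lapply(chains, function(ch) chain_ca(structure, ch)))
  B <- do.call(rbind, lapply(chains, function(ch) chain_ca(reference, ch)))
  if (nrow(A) != nrow(B)) stop("Calpha sets do not match")
  kabsch_superpose(A, B)$rmsd
}

#' Quaternary subunit rotation angle relative to a reference dimer
#'
#' Protocol: superpose chain A of the query onto chain A of the reference
#' (Kabsch on Calpha atoms), apply that transform to the whole query, then
#' compute the Kabsch rotation taking the transformed chain B onto the
#' reference chain B. The unsigned angle
#' arccos((trace(R) - 1) / 2) of that residual rotation is returned in
#' degrees; it is invariant to any global rigid motion of the query.
#'
#' @param structure,reference two-chain dimers with matched Calpha sets
#' @param chains the two chain identifiers (default first two shared)
#' @return angle in degrees, in `[0, 180]`
#' @export
subunit_rotation_angle <- function(structure, reference, chains = NULL) {
  if (is.null(chains)) {
    chains <- intersect(sort(unique(structure$chain)),
                        sort(unique(reference$chain)))
    chains <- head(chains[chains != "W"], 2)
  }
  if (length(chains) != 2L) stop("could not match two chains")
  Aq <- chain_ca(structure, chains[1])
  Ar <- chain_ca(reference, chains[1])
  Bq <- chain_ca(structure, chains[2])
  Br <- chain_ca(reference, chains[2])
  if (nrow(Aq) != nrow(Ar) || nrow(Bq) != nrow(Br)) {
    stop("chain matching failure: unequal Calpha counts")
  }
  fitA <- kabsch_superpose(Aq, Ar)
  Bq_al <- Bq %*% t(fitA$rotation) +
    matrix(fitA$translation, nrow(Bq), 3, byrow = TRUE)
  R <- kabsch_superpose(Bq_al, Br)$rotation
  cosang <- (sum(diag(R)) - 1) / 2
  acos(max(-1, min(1, cosang))) * 180 / pi
}

#' Heme-heme distance
#'
#' Distance between the Fe atoms of the two heme groups. If either Fe is
#' missing the distance between the heme centroids is returned instead and
#' flagged with a warning.
#'
#' @param structure a `trxss_structure` containing exactly two heme
#'   (residue name HEM) groups
#' @return list with `distance` (Angstrom) and `fallback` (TRUE when the
#'   centroid fallback was used)
#' @export
heme_heme_distance <- function(structure) {
  heme <- which(structure$resid == "HEM")
  key <- paste(structure$chain[heme], structure$resno[heme])
  groups <- split(heme, key)
  if (length(groups) != 2L) {
    stop("expected exactly 2 heme groups, found ", length(groups))
  }
  fallback <- FALSE
  pos <- lapply(groups, function(idx) {
    fe <- idx[structure$element[idx] == "FE"]
    if (length(fe) == 1L) {
      coords(structure, fe)[1, ]
    } else {
      fallback <<- TRUE
      atom_centroid(structure, idx)
    }
  })
  if (fallback) {
    warning("heme Fe missing; falling back to heme centroid distance")
  }
  list(distance = sqrt(sum((pos[[1]] - pos[[2]])^2)), fallback = fallback)
}

#' Structural descriptors over a refined candidate ensemble
#'
#' Computes, for each candidate structure, the E-F distance, the subunit
#' rotation angle versus each reference, the heme-heme distance, and the
#' Calpha RMSD versus each reference; summarises each descriptor as
#' mean +/- sd (population standard deviation, matching mean +/- sd
#' reporting of small candidate sets) plus histogram bins.
#'
#' @param ensemble list of `trxss_structure` candidates (e.g.
#'   `result$ensemble` from [run_ensemble()])
#' @param references named list of reference structures; the first is used
#'   for the rotation angle headline
#' @param ef_residues passed to [ef_distance()]
#' @param breaks histogram bin count per descriptor
#' @return list with `per_candidate` (data frame), `summary` (data frame
#'   of mean/sd), and `histograms`
#' @export
ensemble_statistics <- function(ensemble, references, ef_residues = c(66, 102),
                                breaks = 10) {
  if (length(ensemble) == 0L) stop("empty ensemble")
  if (is.null(names(references))) {
    names(references) <- paste0("ref", seq_along(references))
  }
  rows <- lapply(ensemble, function(st) {
    out <- list(
      ef_distance = ef_distance(st, ef_residues)$mean,
      heme_heme = heme_heme_distance(st)$distance)
    for (nm in names(references)) {
      out[[paste0("rotation_vs_", nm)]] <-
        subunit_rotation_angle(st, references[[nm]])
      out[[paste0("rmsd_vs_", nm)]] <- ca_rmsd(st, references[[nm]])
    }
    as.data.frame(out)
  })
  per <- do.call(rbind, rows)
  pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
  summ <- data.frame(
    descriptor = names(per),
    mean = vapply(per, mean, numeric(1)),
    sd = vapply(per, pop_sd, numeric(1)),
    row.names = NULL)
  hists <- lapply(per, function(v) {
    h <- graphics::hist(v, breaks = breaks, plot = FALSE)
    data.frame(mid = h$mids, count = h$counts)
  })
  list(per_candidate = per, summary = summ, histograms = hists)
}
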