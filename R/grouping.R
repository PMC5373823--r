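#' Merge sequential-frame localizations of the same fluorophore
#'
#' A fluorophore that stays on for several consecutive camera frames yields
#' one localization per frame. For display and for density estimation those
#' repeats are merged: chains of localizations appearing in consecutive
#' frames, each within `radius_nm` of the running mean position of the open
#' chain, are replaced by a single localization at the chain's mean position
#' carrying the chain's first frame. Re-appearances separated by a frame gap
#' (reversible photoactivation) are deliberately not merged.
#'
#' Grouping is defined on raw frame streams; a table already grouped (its
#' `grouped` attribute set) is returned unchanged, which makes the operation
#' idempotent.
#'
#' @param locs a [loc_table()].
#' @param radius_nm merge radius (nm); default 80.
#' @return a `loc_table` with attribute `grouped = TRUE`. A ground-truth
#'   `molecule_id` column, when present, is propagated (chain majority).
#' @export
group_sequential <- function(locs, radius_nm = 80) {
  stopifnot(inherits(locs, "loc_table"))
  if (radius_nm <= 0) stop("radius_nm must be positive")
  if (isTRUE(attr(locs, "grouped"))) return(locs)
  pieces <- lapply(unique(locs$channel), function(ch) {
    sub <- locs[locs$channel == ch, , drop = FALSE]
    group_channel_(sub, radius_nm)
  })
  out <- do.call(rbind, pieces)
  out <- loc_table(out$x_nm, out$y_nm, out$frame, out$channel,
                   sigma_nm = if ("sigma_nm" %in% names(out)) out$sigma_nm,
                   molecule_id = if ("molecule_id" %in% names(out)) out$molecule_id)
  attr(out, "grouped") <- TRUE
  out
}

group_channel_ <- function(sub, radius_nm) {
  n <- nrow(sub)
  if (n == 0) return(sub)
  ord <- order(sub$frame)
  sub <- sub[ord, , drop = FALSE]
  has_mid <- "molecule_id" %in% names(sub)
  has_sig <- "sigma_nm" %in% names(sub)
  res <- group_chains_cpp(sub$x_nm, sub$y_nm, sub$frame, radius_nm)
  # res: chain id per localization (1-based)
  cid <- res
  nx <- tapply(sub$x_nm, cid, mean)
  ny <- tapply(sub$y_nm, cid, mean)
  nf <- tapply(sub$frame, cid, min)
  out <- data.frame(x_nm = as.numeric(nx), y_nm = as.numeric(ny),
                    frame = as.integer(nf),
                    channel = sub$channel[1], stringsAsFactors = FALSE)
  if (has_sig) out$sigma_nm <- as.numeric(tapply(sub$sigma_nm, cid, mean))
  if (has_mid) {
    pick_major <- function(v) as.integer(names(which.max(table(v))))
    out$molecule_id <- as.integer(tapply(sub$molecule_id, cid, pick_major))
  }
  out
}
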