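#' @keywords internal
AREAS <- c("V1", "S1", "RL", "AL")
SUBNETS <- c("bottom", "top")

#' Unit bookkeeping table for the four-area network
#'
#' One row per unit in the dense representation: areas V1, S1, RL, AL; within
#' each area the bottom then top subnetwork; within each subnetwork `N_E`
#' excitatory then `N_E` inhibitory units.
#'
#' @param params an [model_params()] object.
#' @return a tibble with columns `unit`, `area`, `subnet`, `type`, `block`
#'   (area-subnet block index 1..8).
#' @export
unit_table <- function(params) {
  n <- params$N_E
  grid <- expand.grid(type = c("E", "I"), subnet = SUBNETS, area = AREAS,
                      stringsAsFactors = FALSE)[, 3:1]
  out <- tibble(
    area = rep(grid$area, each = n),
    subnet = rep(grid$subnet, each = n),
    type = rep(grid$type, each = n)
  )
  out$block <- (match(out$area, AREAS) - 1L) * 2L + match(out$subnet, SUBNETS)
  out$unit <- seq_len(nrow(out))
  out[, c("unit", "area", "subnet", "type", "block")]
}

#' Build the dense connectome of the four-area model
#'
#' Within each area-subnetwork block, units are all-to-all connected with the
#' uniform magnitudes `W_EE`, `W_EI`, `W_IE`, `W_II` (inhibitory sources enter
#' with negative sign).  Inter-areal projections respect subnetwork
#' boundaries (top never contacts bottom), originate from excitatory units
#' only, and are scaled relative to `W_EE`: feedforward V1/S1 -> RL/AL
#' (`ff_scale * W_EE`, contacting E and I), feedback RL -> V1/S1
#' (`fb_scale_RL * W_EE`) and AL -> V1/S1 (`fb_scale_AL * W_EE`),
#' contacting E only.  At these gains the stimulated subnetwork chain
#' settles into a strongly active state within a trial (the association
#' area responding to either sensory modality of its subnetwork), which is
#' why network state is re-initialized at each trial start (see
#' [run_trial()]).  A silenced area has every connection into or out of it
#' removed.
#'
#' @param params an [model_params()] object.
#' @param silenced `"none"`, `"RL"` or `"AL"`.
#' @return an object of class `xmodal_connectome`: list with the dense weight
#'   matrix `W` (entry `[i, j]` is the weight from unit `j` to unit `i`), the
#'   [unit_table()] `units`, and `silenced`.
#' @examples
#' con <- build_connectome(model_params(N_E = 4))
#' dim(con$W)
#' @export
build_connectome <- function(params, silenced = c("none", "RL", "AL")) {
  silenced <- match.arg(silenced)
  units <- unit_table(params)
  nu <- nrow(units)
  W <- matrix(0, nu, nu)
  is_E <- units$type == "E"

  for (b in unique(units$block)) {
    idx <- which(units$block == b)
    e <- idx[is_E[idx]]
    i <- idx[!is_E[idx]]
    W[e, e] <- params$W_EE
    W[e, i] <- -params$W_EI
    W[i, e] <- params$W_IE
    W[i, i] <- -params$W_II
  }

  for (s in SUBNETS) {
    for (src in c("V1", "S1")) {
      src_e <- which(units$area == src & units$subnet == s & is_E)
      for (tgt in c("RL", "AL")) {
        tgt_all <- which(units$area == tgt & units$subnet == s)
        W[tgt_all, src_e] <- params$ff_scale * params$W_EE
      }
    }
    for (src in c("RL", "AL")) {
      src_e <- which(units$area == src & units$subnet == s & is_E)
      fb <- if (src == "RL") params$fb_scale_RL else params$fb_scale_AL
      for (tgt in c("V1", "S1")) {
        tgt_e <- which(units$area == tgt & units$subnet == s & is_E)
        W[tgt_e, src_e] <- fb * params$W_EE
      }
    }
  }

  if (silenced != "none") {
    sil <- which(units$area == silenced)
    W[sil, ] <- 0
    W[, sil] <- 0
  }

  structure(list(W = W, units = units, silenced = silenced),
            class = "xmodal_connectome")
}

#' Block-level summary of a connectome
#'
#' Collapses the dense connectome to block-level structure between the eight
#' area-subnetwork blocks, split by source/target cell type.  Every
#' sub-block of the dense matrix is the sum of a uniform (all-to-all) part
#' and an aligned (diagonal, one-to-one) part; both parts are extracted
#' exactly, which is the representation used by the compiled simulation
#' kernel.  An error is raised if any sub-block deviates from this
#' structure.
#'
#' @param connectome an [build_connectome()] object.
#' @param params the matching [model_params()] object.
#' @return list of eight 8 x 8 matrices: `EE`, `EI`, `IE`, `II` hold the
#'   uniform per-connection weight from each source unit of block `j` to
#'   every target unit of block `i`; `AEE`, `AEI`, `AIE`, `AII` hold the
#'   additional aligned (one-to-one) weight from source unit `u` of block
#'   `j` to target unit `u` of block `i`.
#' @export
connectome_blocks <- function(connectome, params) {
  units <- connectome$units
  W <- connectome$W
  is_E <- units$type == "E"
  nb <- max(units$block)
  take <- function(tgt_E, src_E) {
    u <- matrix(0, nb, nb)
    a <- matrix(0, nb, nb)
    for (i in seq_len(nb)) {
      for (j in seq_len(nb)) {
        ti <- which(units$block == i & (is_E == tgt_E))
        sj <- which(units$block == j & (is_E == src_E))
        blk <- W[ti, sj, drop = FALSE]
        off <- blk[row(blk) != col(blk)]
        dia <- diag(blk)
        if (length(off) > 0 && max(off) - min(off) > 0) {
          stop("non-uniform off-diagonal in connectome sub-block")
        }
        if (max(dia) - min(dia) > 0) {
          stop("non-uniform diagonal in connectome sub-block")
        }
        u[i, j] <- if (length(off) > 0) off[1] else 0
        a[i, j] <- dia[1] - u[i, j]
      }
    }
    list(u = u, a = a)
  }
  ee <- take(TRUE, TRUE); ei <- take(TRUE, FALSE)
  ie <- take(FALSE, TRUE); ii <- take(FALSE, FALSE)
  list(EE = ee$u, EI = ei$u, IE = ie$u, II = ii$u,
       AEE = ee$a, AEI = ei$a, AIE = ie$a, AII = ii$a)
}

#' External stimulus input vector
#'
#' Returns the per-unit external drive `I(t)` during the stimulus period: a
#' step of amplitude `c_s` delivered to every excitatory unit of one
#' subnetwork of one sensory area, zero elsewhere.  Driving the local
#' inhibitory pool as well would cancel most of the stimulus drive and the
#' decision variables would almost never reach threshold within the
#' stimulus period.
#'
#' @param connectome an [build_connectome()] object.
#' @param area `"V1"` or `"S1"`.
#' @param location `"bottom"` (s1) or `"top"` (s2).
#' @param params an [model_params()] object.
#' @return numeric vector of length `nrow(connectome$units)`.
#' @export
stimulus_input <- function(connectome, area = c("S1", "V1"),
                           location = c("bottom", "top"), params) {
  area <- match.arg(area)
  location <- match.arg(location)
  units <- connectome$units
  I <- numeric(nrow(units))
  I[units$area == area & units$subnet == location &
      units$type == "E"] <- params$c_s
  I
}
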