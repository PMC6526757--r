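# Small trees built in code for unit tests.

single_segment_tree <- function(length_mm = 100, d_prox = 3, d_dist = 2.5,
                                artery = "LAD") {
  seg <- data.frame(id = "s1", artery = artery, parent_id = NA_character_,
                    length_mm = length_mm, d_prox_mm = d_prox,
                    d_dist_mm = d_dist,
                    territory = if (artery == "RCA") "RV" else "NA",
                    stringsAsFactors = FALSE)
  coronary_tree("unit", seg)
}

# straight LAD chain of n equal segments
chain_tree <- function(n = 3, seg_len = 30, d0 = 3, d1 = 2) {
  d <- seq(d0, d1, length.out = n + 1)
  seg <- data.frame(id = paste0("c", seq_len(n)), artery = "LAD",
                    parent_id = c(NA_character_, paste0("c", seq_len(n - 1))),
                    length_mm = rep(seg_len, n), d_prox_mm = d[-(n + 1)],
                    d_dist_mm = d[-1], territory = "NA",
                    stringsAsFactors = FALSE)
  coronary_tree("chain", seg)
}

# LAD tree with one bifurcation into two terminal branches
forked_tree <- function(l_left = 40, l_right = 40) {
  seg <- data.frame(
    id = c("trunk", "left", "right"), artery = "LAD",
    parent_id = c(NA_character_, "trunk", "trunk"),
    length_mm = c(50, l_left, l_right),
    d_prox_mm = c(3.5, 2.5, 2.5), d_dist_mm = c(3.0, 2.0, 2.0),
    territory = "NA", stringsAsFactors = FALSE)
  coronary_tree("fork", seg)
}

uniform_outlets <- function(tree, resistance) {
  ids <- terminal_segments(tree)
  ob <- data.frame(outlet_segment_id = ids,
                   artery = tree$segments$artery[match(ids, tree$segments$id)],
                   resistance = resistance,
                   collateral_enabled = FALSE,
                   collateral_threshold = NA_real_,
                   collateral_resistance = NA_real_,
                   stringsAsFactors = FALSE)
  class(ob) <- c("outlet_boundaries", "data.frame")
  ob
}

# cheap structural fingerprint used for purity assertions
digest_df <- function(x) paste(deparse(x), collapse = "\n")

# independent junction-balance check on a solved state: inflow minus child
# and outlet flows at each segment's distal node, in mL/s
junction_imbalance <- function(tree, state, outlets, venous_pressure = 0) {
  s <- tree$segments
  vapply(seq_len(nrow(s)), function(i) {
    id <- s$id[i]
    kids <- s$id[!is.na(s$parent_id) & s$parent_id == id]
    q_out <- 0
    j <- match(id, outlets$outlet_segment_id)
    if (!is.na(j)) {
      r_eff <- collateral_adjust(outlets[j, ], state$node_pressures[[id]])
      if (is.finite(r_eff))
        q_out <- (state$node_pressures[[id]] - venous_pressure) / r_eff
    }
    state$segment_flows[[id]] - sum(state$segment_flows[kids]) - q_out
  }, numeric(1))
}
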