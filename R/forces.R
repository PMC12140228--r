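#' Repulsion/adhesion force between two overlapping circles
#'
#' Soft excluded-volume contact: repulsion proportional to the overlap
#' (`k_R * overlap`) opposed, while the circles touch, by an adhesive pull of
#' constant magnitude `H` (the default law) or proportional magnitude
#' (`H * overlap`, the alternative law). The net force may be attractive
#' when `k_R * overlap < H`; two adhering circles therefore relax to a
#' stable overlap depth of `H / k_R` under the constant law.
#'
#' @param contact A `contact_result` from [circle_circle_contact()].
#' @param H Adhesion strength, nN.
#' @inheritParams model_params
#' @return Length-2 force (nN) on the first (queried) circle; the partner
#'   receives the opposite.
#' @export
pair_force <- function(contact, H, k_R, adhesion_law = "constant") {
  if (contact$overlap <= 0) return(c(0, 0))
  mag <- if (adhesion_law == "constant") k_R * contact$overlap - H
         else (k_R - H) * contact$overlap
  mag * contact$normal
}

#' Adhesion strength for a circle pair
#'
#' The pairing table of the model: neuroblasts of different cells adhere
#' with `H_N(t)`; units of one astrocyte with `H_a` (strong, so an
#' astrocyte never splits); units of different astrocytes with `H_A`
#' (weak but non-zero); neuroblast-astrocyte contacts are repulsion-only.
#' Soma and tip of the same cell do not interact by contact at all - their
#' only coupling is the process spring.
#'
#' @param kind_a,kind_b `"neuroblast"` or `"astrocyte"`.
#' @param id_a,id_b Owning cell/astrocyte ids.
#' @param H_N_t Current neuroblast-neuroblast adhesion, nN.
#' @inheritParams model_params
#' @return Adhesion in nN, or `NA` if the pair does not interact (same-cell
#'   soma-tip pair).
#' @export
select_adhesion <- function(kind_a, id_a, kind_b, id_b,
                            H_N_t = 2.22, H_A = 0.56, H_a = 22.2) {
  if (kind_a == "neuroblast" && kind_b == "neuroblast") {
    if (id_a == id_b) return(NA_real_)
    return(H_N_t)
  }
  if (kind_a == "astrocyte" && kind_b == "astrocyte") {
    return(if (id_a == id_b) H_a else H_A)
  }
  0
}

#' Via-process repulsion with lever-arm distribution
#'
#' Repulsion between a foreign circle and the process rectangle of a
#' neuroblast. The circle is pushed away from the closest point of the
#' segment; the reaction is distributed to the owner's soma and tip with
#' lever weights `(1 - s)` and `s`, where `s` is the contact parameter
#' (0 at the soma centre, 1 at the tip centre). Contacts whose closest
#' point clamps to an endpoint are handled entirely by the circle-circle
#' term, so the via-process force is zero there (no double counting).
#'
#' @param soma,tip Owner's circle centres (wrapped, um).
#' @param other_center,other_radius The foreign circle.
#' @inheritParams model_params
#' @inheritParams wrap_position
#' @return List with `on_soma`, `on_tip`, `on_other` (length-2 forces, nN)
#'   and the contact parameter `s` (NA when there is no via-process
#'   contact). The three forces always sum to zero.
#' @export
process_forces <- function(soma, tip, other_center, other_radius,
                           k_R, w, field) {
  zero <- list(on_soma = c(0, 0), on_tip = c(0, 0), on_other = c(0, 0),
               s = NA_real_)
  ct <- circle_segment_contact(other_center, other_radius, soma, tip, w, field)
  s <- ct$segment_param
  if (ct$overlap <= 0 || s <= 0 || s >= 1 || isTRUE(ct$degenerate)) return(zero)
  f <- k_R * ct$overlap * ct$normal
  list(on_soma = -(1 - s) * f, on_tip = -s * f, on_other = f, s = s)
}

#' Assemble the full force ledger (reference implementation)
#'
#' Plain O(n^2) double loop over all circle pairs (somas, tips, astrocytic
#' units) plus all (process, foreign circle) pairs, in R. This is the
#' reference against which the compiled engine is checked; it is exact but
#' slow, so use it on small states only. Spring forces are included.
#' Process-process contacts do not occur for in-range parameters and are
#' not computed.
#'
#' @param neuroblasts Tibble with columns `cell_id`, `soma_x`, `soma_y`,
#'   `tip_x`, `tip_y` and `l_target` (per-cell spring target, um).
#' @param astrocytes Tibble with columns `astro_id`, `unit`, `x`, `y`,
#'   `radius` (zero rows allowed).
#' @param params A [model_params()].
#' @param H_N_t Current neuroblast-neuroblast adhesion, nN.
#' @inheritParams wrap_position
#' @return A tibble ledger: `kind`, `id`, `role` (`"soma"`, `"tip"` or unit
#'   number), `fx`, `fy`. The ledger sums to zero.
#' @export
assemble_forces <- function(neuroblasts, astrocytes, params, field,
                            H_N_t = params$H_N) {
  p <- params
  n <- nrow(neuroblasts)
  m <- if (is.null(astrocytes)) 0L else nrow(astrocytes)
  # circle table: 2n neuroblast circles then m units
  circ <- tibble::tibble(
    kind = c(rep(c("neuroblast"), 2 * n), rep("astrocyte", m)),
    id = c(rep(neuroblasts$cell_id, each = 2),
           if (m) astrocytes$astro_id else integer()),
    role = c(rep(c("soma", "tip"), n),
             if (m) as.character(astrocytes$unit) else character()),
    x = c(rbind(neuroblasts$soma_x, neuroblasts$tip_x),
          if (m) astrocytes$x else numeric()),
    y = c(rbind(neuroblasts$soma_y, neuroblasts$tip_y),
          if (m) astrocytes$y else numeric()),
    r = c(rep(c(p$r_S, p$r_T), n), if (m) astrocytes$radius else numeric()))
  nc <- nrow(circ)
  fx <- numeric(nc)
  fy <- numeric(nc)
  if (nc > 1) {
    for (i in seq_len(nc - 1)) {
      for (j in (i + 1):nc) {
        if (circ$kind[i] == "neuroblast" && circ$kind[j] == "neuroblast" &&
            circ$id[i] == circ$id[j]) next
        H <- select_adhesion(circ$kind[i], circ$id[i], circ$kind[j],
                             circ$id[j], H_N_t, p$H_A, p$H_a)
        ct <- circle_circle_contact(c(circ$x[i], circ$y[i]), circ$r[i],
                                    c(circ$x[j], circ$y[j]), circ$r[j],
                                    field)
        if (isTRUE(ct$degenerate)) {
          stop("coincident circle centres in reference assembly")
        }
        f <- pair_force(ct, H, p$k_R, p$adhesion_law)
        fx[i] <- fx[i] + f[1]; fy[i] <- fy[i] + f[2]
        fx[j] <- fx[j] - f[1]; fy[j] <- fy[j] - f[2]
      }
    }
  }
  # via-process contacts: every neuroblast's process vs every foreign circle
  for (i in seq_len(n)) {
    soma <- c(neuroblasts$soma_x[i], neuroblasts$soma_y[i])
    tip <- c(neuroblasts$tip_x[i], neuroblasts$tip_y[i])
    i_soma <- 2 * i - 1
    i_tip <- 2 * i
    for (j in seq_len(nc)) {
      if (circ$kind[j] == "neuroblast" && circ$id[j] == neuroblasts$cell_id[i]) next
      pf <- process_forces(soma, tip, c(circ$x[j], circ$y[j]), circ$r[j],
                           p$k_R, p$w, field)
      fx[j] <- fx[j] + pf$on_other[1]; fy[j] <- fy[j] + pf$on_other[2]
      fx[i_soma] <- fx[i_soma] + pf$on_soma[1]
      fy[i_soma] <- fy[i_soma] + pf$on_soma[2]
      fx[i_tip] <- fx[i_tip] + pf$on_tip[1]
      fy[i_tip] <- fy[i_tip] + pf$on_tip[2]
    }
  }
  # process spring
  for (i in seq_len(n)) {
    sp <- spring_forces(c(neuroblasts$soma_x[i], neuroblasts$soma_y[i]),
                        c(neuroblasts$tip_x[i], neuroblasts$tip_y[i]),
                        neuroblasts$l_target[i], p$k_P, field)
    i_soma <- 2 * i - 1
    i_tip <- 2 * i
    fx[i_soma] <- fx[i_soma] + sp$on_soma[1]
    fy[i_soma] <- fy[i_soma] + sp$on_soma[2]
    fx[i_tip] <- fx[i_tip] + sp$on_tip[1]
    fy[i_tip] <- fy[i_tip] + sp$on_tip[2]
  }
  circ$fx <- fx
  circ$fy <- fy
  circ[, c("kind", "id", "role", "fx", "fy")]
}
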