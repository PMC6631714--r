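# Ligand 2D circular-fragment counts (Morgan-like rooted environments) and
# Hybrid (CF + fragment) vector assembly.
#
# A fragment is the canonical string of the rooted bond environment of a
# heavy atom up to a sphere radius (bond depth); counts are aggregated per
# canonical name, hydrogens suppressed.  Conformer-independent by
# construction: two poses of one ligand share the fragment block.

#' Define a circular-fragment scheme
#'
#' @param min_sphere,max_sphere sphere (bond-depth) range, 0 <= min <= max <= 4.
#' @param atom_label `"element"`, `"element_charge"` (element plus a formal
#'   charge flag) or `"pharmacophore"` (donor/acceptor/charge/hydrophobe
#'   classes).
#' @param id optional scheme identifier.
#' @return object of class `FragmentScheme`.
#' @export
fragment_scheme <- function(min_sphere = 1, max_sphere = 2,
                            atom_label = c("element", "element_charge",
                                           "pharmacophore"),
                            id = NULL) {
  atom_label <- match.arg(atom_label)
  if (!(min_sphere >= 0 && min_sphere <= max_sphere && max_sphere <= 4))
    stopf("require 0 <= min_sphere <= max_sphere <= 4")
  if (is.null(id))
    id <- sprintf("circ-%d-%d-%s", min_sphere, max_sphere, atom_label)
  structure(list(min_sphere = min_sphere, max_sphere = max_sphere,
                 atom_label = atom_label, id = id),
            class = "FragmentScheme")
}

#' Default grid of candidate fragment schemes
#'
#' Sphere ranges 1-1, 1-2, 2-2, 1-3 crossed with the three atom-label
#' modes: 12 schemes.  The circular spheres-1-2 element+charge scheme (the
#' class selected for Hybrid maps) is among them.
#'
#' @return list of [fragment_scheme()] objects.
#' @export
fragment_scheme_grid <- function() {
  out <- list()
  for (rng in list(c(1, 1), c(1, 2), c(2, 2), c(1, 3)))
    for (lab in c("element", "element_charge", "pharmacophore"))
      out[[length(out) + 1]] <- fragment_scheme(rng[1], rng[2], lab)
  out
}

frag_atom_labels <- function(lig, scheme) {
  a <- lig$atoms
  switch(scheme$atom_label,
    element = a$element,
    element_charge = paste0(a$element,
                            ifelse(a$formal_charge != 0,
                                   sprintf("%+d", a$formal_charge), "")),
    pharmacophore = {
      # heavy-atom pharmacophore classes; donor = heavy atom carrying a donor H
      el <- a$element
      don_heavy <- rep(FALSE, nrow(a))
      if (nrow(lig$bonds)) {
        for (b in seq_len(nrow(lig$bonds))) {
          i <- lig$bonds$i[b]; j <- lig$bonds$j[b]
          if (el[i] == "H" && a$is_hbd[i]) don_heavy[j] <- TRUE
          if (el[j] == "H" && a$is_hbd[j]) don_heavy[i] <- TRUE
        }
      }
      lab <- ifelse(a$formal_charge > 0, "P",
             ifelse(a$formal_charge < 0, "M",
             ifelse(don_heavy & a$is_hba, "B",
             ifelse(don_heavy, "D",
             ifelse(a$is_hba, "A",
             ifelse(el == "C", "Y", "X"))))))
      lab
    })
}

bond_symbol <- function(order) {
  o <- as.character(order)
  ifelse(o %in% c("2"), "=", ifelse(o %in% c("3"), "#",
    ifelse(o %in% c("1"), "", "~")))
}

#' Circular-fragment counts of a ligand
#'
#' For every heavy atom with at least one heavy neighbor and every sphere
#' radius in the scheme's range, the canonical rooted-environment string is
#' emitted (children recursively expanded, sorted, unexpanded leaves bare,
#' expanded nodes always parenthesised so the radius is encoded in the
#' name); counts are aggregated per name.  Disconnected ligands are
#' processed per component with a warning.
#'
#' @param lig a [ligand()] with bond graph.
#' @param scheme a [fragment_scheme()].
#' @return named integer vector of fragment counts.
#' @export
circular_fragments <- function(lig, scheme = fragment_scheme()) {
  a <- lig$atoms
  heavy <- which(a$element != "H")
  labs <- frag_atom_labels(lig, scheme)
  # heavy-atom adjacency with bond symbols
  adj <- lapply(seq_len(nrow(a)), function(i) integer(0))
  sym <- lapply(seq_len(nrow(a)), function(i) character(0))
  if (nrow(lig$bonds)) {
    for (b in seq_len(nrow(lig$bonds))) {
      i <- lig$bonds$i[b]; j <- lig$bonds$j[b]
      if (a$element[i] == "H" || a$element[j] == "H") next
      s <- bond_symbol(lig$bonds$order[b])
      adj[[i]] <- c(adj[[i]], j); sym[[i]] <- c(sym[[i]], s)
      adj[[j]] <- c(adj[[j]], i); sym[[j]] <- c(sym[[j]], s)
    }
  }
  if (length(heavy) > 1) {
    seen <- rep(FALSE, nrow(a)); seen[-heavy] <- TRUE
    queue <- heavy[1]; seen[heavy[1]] <- TRUE
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- adj[[v]][!seen[adj[[v]]]]
      seen[nb] <- TRUE; queue <- c(queue, nb)
    }
    if (!all(seen))
      warnf("ligand '%s' is disconnected: fragments computed per component",
            lig$ligand_id)
  }
  canon <- function(v, remaining, from) {
    if (remaining == 0) return(labs[v])
    kids <- character(0)
    for (t in seq_along(adj[[v]])) {
      w <- adj[[v]][t]
      if (w == from) next
      kids <- c(kids, paste0(sym[[v]][t], canon(w, remaining - 1, v)))
    }
    paste0(labs[v], "(", paste(sort(kids), collapse = ","), ")")
  }
  counts <- integer(0)
  for (v in heavy) {
    for (L in scheme$min_sphere:scheme$max_sphere) {
      if (L > 0 && !length(adj[[v]])) next  # no heavy neighbor: no environment
      nm <- if (L == 0) labs[v] else canon(v, L, 0L)
      counts[nm] <- (if (is.na(counts[nm])) 0L else counts[nm]) + 1L
    }
  }
  counts
}

#' Fixed fragment vocabulary over a training ligand set
#'
#' @param fragment_list list of named count vectors from
#'   [circular_fragments()].
#' @return character vector of fragment names in lexicographic order.
#' @export
fragment_vocabulary <- function(fragment_list) {
  sort(unique(unlist(lapply(fragment_list, names))))
}

#' Assemble a Hybrid (CF + fragment) vector
#'
#' CF slots first, then fragment counts in vocabulary order.
#' Out-of-vocabulary fragments of new ligands are dropped with a warning
#' stating how many.
#'
#' @param cf a [compute_cf()] vector.
#' @param fragments named count vector from [circular_fragments()].
#' @param vocabulary ordered fragment names fixed before any map fitting.
#' @return named numeric vector of class `HyVector`, length
#'   `|CF| + |vocabulary|`.
#' @export
build_hy <- function(cf, fragments, vocabulary) {
  fcounts <- setNames(numeric(length(vocabulary)), vocabulary)
  hit <- names(fragments) %in% vocabulary
  if (any(!hit))
    warnf("%d out-of-vocabulary fragment(s) dropped", sum(!hit))
  fcounts[names(fragments)[hit]] <- fragments[hit]
  v <- c(as.numeric(cf), fcounts)
  frag_names <- if (length(vocabulary)) paste0("frag:", vocabulary) else character(0)
  names(v) <- c(names(cf), frag_names)
  structure(v, class = "HyVector",
            ligand_id = attr(cf, "ligand_id"),
            conformer_id = attr(cf, "conformer_id"),
            n_cf = length(cf), n_frag = length(vocabulary))
}

#' Write a fragment vocabulary as a JSON sidecar
#' @param vocabulary character vector of fragment names.
#' @param path output path.
#' @export
write_vocabulary <- function(vocabulary, path) {
  jsonlite::write_json(as.list(setNames(seq_along(vocabulary), vocabulary)),
                       path, auto_unbox = TRUE)
  invisible(path)
}

#' Read a fragment vocabulary JSON sidecar
#' @param path JSON path.
#' @return character vector of fragment names in stored column order.
#' @export
read_vocabulary <- function(path) {
  v <- jsonlite::read_json(path)
  names(v)[order(unlist(v))]
}
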