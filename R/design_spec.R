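# The design-specification language: a small YAML dialect describing
# entities, designed segments, covalent bonds, structure groups, binding-site
# and secondary-structure annotations, plus the conditioning featurization
# and the training-time task/conditioning sampler.

#' Parse a design specification
#'
#' Reads the YAML dialect:
#' \preformatted{
#' entities:
#'   - id: A
#'     type: protein            # protein | dna | rna | ligand
#'     sequence: MKV...         # optional
#'     design:                  # optional designed segments
#'       - {range: [5, 12]}     # design residues 5..12
#'       - {length: [80, 140]}  # designed segment, length sampled later
#' bonds:
#'   - atom1: {entity: A, residue: 3, atom: SG, res_type: CYS}
#'     atom2: {entity: A, residue: 10, atom: SG, res_type: CYS}
#' groups:
#'   - name: target
#'     members: [{entity: B}]            # optionally {entity: B, range: [i, j]}
#' binding:
#'   - {entity: B, residues: [5, 6], label: binding}   # or not_binding
#' secondary_structure:
#'   - {entity: A, residues: [5, 6, 7], label: helix}  # helix | sheet | coil
#' }
#'
#' Validation enforces: referenced entities exist; a covalent bond touching
#' a designed residue requires that residue's identity (`res_type`); no
#' residue is labelled both binding and not_binding; structure groups are
#' disjoint residue sets. Length ranges are retained unsampled (see
#' [sample_design_lengths()]).
#'
#' @param text YAML string (or a file path to one).
#' @return object of class `bk_design_spec`.
#' @export
parse_spec <- function(text) {
  # YAML 1.1 would read the bare atom/anchor names N and Y as booleans;
  # keep those as strings while preserving ordinary booleans.
  bool_handler <- function(x) {
    if (toupper(x) %in% c("Y", "N")) x else tolower(x) %in% c("yes", "true", "on", "y")
  }
  handlers <- list("bool#yes" = bool_handler, "bool#no" = bool_handler)
  doc <- if (length(text) == 1L && !grepl("\n", text) && file.exists(text))
    yaml::read_yaml(text, handlers = handlers)
  else yaml::yaml.load(text, handlers = handlers)
  if (is.null(doc$entities) || !length(doc$entities))
    stop("design spec must declare at least one entity")

  entities <- lapply(doc$entities, function(e) {
    if (is.null(e$id)) stop("entity without id")
    type <- e$type %||% "protein"
    if (!type %in% c("protein", "dna", "rna", "ligand"))
      stop("unknown entity type: ", type)
    list(id = as.character(e$id), type = type,
         sequence = e$sequence %||% NULL)
  })
  ids <- vapply(entities, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("duplicate entity ids")
  names(entities) <- ids
  check_entity <- function(id, where) {
    if (!as.character(id) %in% ids)
      stop(sprintf("unknown entity '%s' referenced in %s", id, where))
    as.character(id)
  }

  design_segments <- list()
  for (e in doc$entities) {
    for (seg in e$design %||% list()) {
      if (!is.null(seg$range)) {
        if (length(seg$range) != 2 || seg$range[1] > seg$range[2])
          stop("invalid design range for entity ", e$id)
        design_segments[[length(design_segments) + 1L]] <-
          list(entity = as.character(e$id), kind = "range",
               from = as.integer(seg$range[1]), to = as.integer(seg$range[2]),
               res_types = seg$res_types %||% NULL)
      } else if (!is.null(seg$length)) {
        rng <- as.integer(if (length(seg$length) == 1) rep(seg$length, 2) else seg$length)
        if (length(rng) != 2 || rng[1] > rng[2] || rng[1] < 1)
          stop("invalid design length range for entity ", e$id)
        design_segments[[length(design_segments) + 1L]] <-
          list(entity = as.character(e$id), kind = "length",
               min = rng[1], max = rng[2])
      } else stop("design segment must give 'range' or 'length' (entity ", e$id, ")")
    }
  }

  is_design_residue <- function(entity, residue) {
    for (seg in design_segments)
      if (seg$entity == entity && seg$kind == "range" &&
          residue >= seg$from && residue <= seg$to) return(seg)
    NULL
  }

  bonds <- lapply(doc$bonds %||% list(), function(b) {
    ends <- lapply(c("atom1", "atom2"), function(k) {
      a <- b[[k]]
      if (is.null(a)) stop("bond must give atom1 and atom2")
      ent <- check_entity(a$entity, "bond")
      end <- list(entity = ent, residue = as.integer(a$residue),
                  atom = as.character(a$atom),
                  res_type = if (is.null(a$res_type)) NULL else
                    normalize_res_type(a$res_type))
      seg <- is_design_residue(end$entity, end$residue)
      if (!is.null(seg) && is.null(end$res_type))
        stop(sprintf(paste0(
          "bond endpoint %s:%d touches a designed residue; the identity of ",
          "residues containing bonded atoms must be specified (res_type)"),
          end$entity, end$residue))
      end
    })
    list(atom1 = ends[[1]], atom2 = ends[[2]])
  })

  groups <- lapply(doc$groups %||% list(), function(g) {
    if (is.null(g$name)) stop("structure group without name")
    members <- lapply(g$members %||% list(), function(m) {
      ent <- check_entity(m$entity, paste0("group '", g$name, "'"))
      list(entity = ent,
           range = if (is.null(m$range)) NULL else as.integer(m$range))
    })
    if (!length(members)) stop("structure group '", g$name, "' has no members")
    list(name = as.character(g$name), members = members)
  })
  check_groups_disjoint(groups)

  labels <- function(block, allowed, where) {
    lapply(doc[[block]] %||% list(), function(x) {
      ent <- check_entity(x$entity, where)
      lab <- as.character(x$label)
      if (!lab %in% allowed)
        stop(sprintf("invalid %s label '%s'", where, lab))
      list(entity = ent, residues = as.integer(x$residues), label = lab)
    })
  }
  binding <- labels("binding", c("binding", "not_binding"), "binding")
  ss <- labels("secondary_structure", c("helix", "sheet", "coil"),
               "secondary-structure")

  # a residue must not be both binding and not_binding
  tab <- list()
  for (b in binding) for (r in b$residues) {
    key <- paste(b$entity, r)
    if (!is.null(tab[[key]]) && tab[[key]] != b$label)
      stop("residue ", key, " labelled both binding and not_binding")
    tab[[key]] <- b$label
  }

  structure(list(entities = entities, design_segments = design_segments,
                 bonds = bonds, groups = groups, binding = binding, ss = ss),
            class = "bk_design_spec")
}

check_groups_disjoint <- function(groups) {
  res_seen <- character(0)
  whole_seen <- character(0)
  for (g in groups) for (m in g$members) {
    if (is.null(m$range)) {
      if (m$entity %in% whole_seen ||
          any(startsWith(res_seen, paste0(m$entity, " "))))
        stop("structure groups are not disjoint (entity ", m$entity, ")")
      whole_seen <- c(whole_seen, m$entity)
    } else {
      keys <- paste(m$entity, seq(m$range[1], m$range[2]))
      if (m$entity %in% whole_seen || any(keys %in% res_seen))
        stop("structure groups are not disjoint (entity ", m$entity, ")")
      res_seen <- c(res_seen, keys)
    }
  }
  invisible(TRUE)
}

#' Sample concrete design lengths
#'
#' Replaces every length-range design segment by a uniform draw from its
#' range; range segments are untouched. Deterministic given the seed.
#'
#' @param spec a [parse_spec()] result.
#' @param seed RNG seed.
#' @return the spec with all `length` segments made concrete (field
#'   `sampled_length`).
#' @export
sample_design_lengths <- function(spec, seed = 1) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  spec$design_segments <- lapply(spec$design_segments, function(seg) {
    if (seg$kind == "length") {
      if (seg$max < seg$min) stop("empty length range")
      seg$sampled_length <- if (seg$min == seg$max) seg$min else
        sample(seg$min:seg$max, 1)
    }
    seg
  })
  spec
}

#' Featurize conditioning inputs
#'
#' Turns a concrete design spec plus a structure into the model-facing
#' conditioning features: a pairwise atom-distance matrix with entries
#' present only within a structure group (masked `NA` elsewhere), a
#' symmetric boolean covalent-bond matrix with an empty diagonal, and
#' per-token flags (is_design, binding, not_binding, secondary-structure
#' one-hot).
#'
#' @param spec a [parse_spec()] result (entity ids = chain ids).
#' @param structure a [bk_structure()] consistent with the spec.
#' @return object of class `bk_conditioning_features`: list with
#'   `pair_distance` (n_atoms x n_atoms), `bond_matrix`, `token_flags`.
#' @export
featurize_conditioning <- function(spec, structure) {
  a <- structure$atoms
  n <- nrow(a)
  xyz <- coords(structure)

  pair_distance <- matrix(NA_real_, n, n)
  for (g in spec$groups) {
    rows <- integer(0)
    for (m in g$members) {
      sel <- a$chain == m$entity
      if (!is.null(m$range))
        sel <- sel & a$res_index >= m$range[1] & a$res_index <= m$range[2]
      r <- which(sel)
      if (!length(r))
        stop("structure group '", g$name, "' references atoms missing from the structure")
      rows <- c(rows, r)
    }
    d <- as.matrix(stats::dist(xyz[rows, , drop = FALSE]))
    pair_distance[rows, rows] <- d
  }

  bond_matrix <- matrix(FALSE, n, n)
  for (b in spec$bonds) {
    ij <- vapply(list(b$atom1, b$atom2), function(end) {
      j <- which(a$chain == end$entity & a$res_index == end$residue &
                   a$atom_name == end$atom)
      if (length(j) != 1L)
        stop(sprintf("bond atom %s:%d:%s not found in structure",
                     end$entity, end$residue, end$atom))
      j
    }, integer(1))
    bond_matrix[ij[1], ij[2]] <- TRUE
    bond_matrix[ij[2], ij[1]] <- TRUE
  }

  tk <- tokenize(structure)
  tokens <- tk$tokens
  flag <- function(labels, lab) {
    out <- logical(nrow(tokens))
    for (x in labels) if (x$label == lab)
      out <- out | (tokens$chain == x$entity & tokens$res_index %in% x$residues)
    out
  }
  in_design <- logical(nrow(tokens))
  for (seg in spec$design_segments) if (seg$kind == "range")
    in_design <- in_design | (tokens$chain == seg$entity &
                                tokens$res_index >= seg$from &
                                tokens$res_index <= seg$to)
  token_flags <- data.frame(
    token_index = tokens$token_index,
    is_design = in_design | tokens$is_design,
    binding = flag(spec$binding, "binding"),
    not_binding = flag(spec$binding, "not_binding"),
    ss_helix = flag(spec$ss, "helix"),
    ss_sheet = flag(spec$ss, "sheet"),
    ss_coil = flag(spec$ss, "coil")
  )
  structure(list(pair_distance = pair_distance, bond_matrix = bond_matrix,
                 token_flags = token_flags),
            class = "bk_conditioning_features")
}

#' Serialize / deserialize conditioning features as JSON
#'
#' Masked distance entries become `null`; the round trip preserves masks,
#' bonds and flags exactly.
#'
#' @param features a [featurize_conditioning()] result.
#' @param json JSON string from `features_to_json()`.
#' @export
features_to_json <- function(features) {
  jsonlite::toJSON(list(
    pair_distance = features$pair_distance,
    bond_matrix = features$bond_matrix,
    token_flags = features$token_flags
  ), digits = NA, na = "null")
}

#' @rdname features_to_json
#' @export
features_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  structure(list(
    pair_distance = matrix(as.numeric(x$pair_distance),
                           nrow = nrow(x$pair_distance)),
    bond_matrix = matrix(as.logical(x$bond_matrix), nrow = nrow(x$bond_matrix)),
    token_flags = as.data.frame(x$token_flags)
  ), class = "bk_conditioning_features")
}

#' Sample a training task and its conditioning
#'
#' Draws one of the training tasks (folding, binder design, motif
#' scaffolding, unconditional design) with the configured probabilities,
#' restricted to tasks the structure supports: binder design needs more
#' than a single protein monomer. Builds the design-token mask for the task
#' (folding: none; binder: one protein chain, optionally only its
#' interface; motif: a contiguous token crop or its complement;
#' unconditional: everything) and samples conditioning channels, each
#' independently dropped with probability `p_drop`: structure groups from
#' random crops of the non-designed part, binding labels from proximity of
#' target residues to designed atoms (within `bind_cutoff` binding, beyond
#' `notbind_cutoff` eligible for not_binding), and random
#' secondary-structure labels on design tokens.
#'
#' @param structure a [bk_structure()].
#' @param task_probs named probabilities for
#'   `c("folding", "binder_design", "motif_scaffolding", "unconditional")`.
#' @param p_drop independent drop-out probability per conditioning channel.
#' @param bind_cutoff,notbind_cutoff proximity cutoffs in Angstrom.
#' @param seed RNG seed.
#' @return object of class `bk_training_task`: list with `task_kind`,
#'   `design_mask` (logical per token), `conditioning`.
#' @export
sample_training_task <- function(structure,
                                 task_probs = c(folding = 0.4,
                                                binder_design = 0.3,
                                                motif_scaffolding = 0.2,
                                                unconditional = 0.1),
                                 p_drop = 0.5, bind_cutoff = 8,
                                 notbind_cutoff = 12, seed = NULL) {
  if (!is.null(seed)) { old <- .Random.seed_save(); on.exit(.Random.seed_restore(old)); set.seed(seed) }
  tk <- tokenize(structure)
  tokens <- tk$tokens
  n_tok <- nrow(tokens)
  prot_chains <- structure$chains$chain_id[structure$chains$polymer_class == "protein"]
  single_monomer <- nrow(structure$chains) == 1L && length(prot_chains) == 1L

  allowed <- names(task_probs)
  if (single_monomer) allowed <- setdiff(allowed, "binder_design")
  p <- task_probs[allowed] / sum(task_probs[allowed])
  task <- sample(allowed, 1, prob = p)

  mask <- logical(n_tok)
  if (task == "binder_design") {
    chain <- if (length(prot_chains) == 1) prot_chains else sample(prot_chains, 1)
    mask <- tokens$chain == chain
    if (stats::runif(1) < 0.5) {   # interface-only variant
      iface <- interface_token_mask(structure, tokens, chain, bind_cutoff)
      if (any(iface)) mask <- iface
    }
  } else if (task == "motif_scaffolding") {
    len <- max(1L, as.integer(stats::runif(1, 0.2, 0.6) * n_tok))
    start <- sample(seq_len(n_tok - len + 1L), 1)
    inside <- seq(start, start + len - 1L)
    mask[inside] <- TRUE
    if (stats::runif(1) < 0.5) mask <- !mask  # scaffold the motif instead
  } else if (task == "unconditional") {
    mask <- rep(TRUE, n_tok)
  }

  conditioning <- list(groups = list(), binding = NULL, ss = NULL)
  non_design <- which(!mask)
  if (length(non_design) && stats::runif(1) >= p_drop) {
    n_groups <- sample(1:2, 1)
    pool <- non_design
    for (g in seq_len(n_groups)) {
      if (!length(pool)) break
      take <- sample(length(pool), max(1L, as.integer(length(pool) / n_groups / 2)))
      conditioning$groups[[g]] <- sort(pool[take])
      pool <- setdiff(pool, pool[take])
    }
  }
  if (any(mask) && any(!mask) && stats::runif(1) >= p_drop) {
    prox <- token_proximity_to_design(structure, tokens, mask)
    binding <- ifelse(!mask & prox <= bind_cutoff, "binding",
                      ifelse(!mask & prox > notbind_cutoff, "not_binding", NA))
    keep <- !is.na(binding) & stats::runif(n_tok) < 0.5
    binding[!keep] <- NA
    conditioning$binding <- binding
  }
  if (any(mask) && stats::runif(1) >= p_drop) {
    ss <- rep(NA_character_, n_tok)
    pick <- which(mask & stats::runif(n_tok) < 0.3)
    ss[pick] <- sample(c("helix", "sheet", "coil"), length(pick), replace = TRUE)
    conditioning$ss <- ss
  }
  structure(list(task_kind = task, design_mask = mask,
                 conditioning = conditioning),
            class = "bk_training_task")
}

token_centroids <- function(structure, tokens) {
  tk <- tokenize(structure)
  xyz <- coords(structure)
  t(vapply(tokens$token_index, function(i)
    colMeans(xyz[tk$atom_token == i, , drop = FALSE]), numeric(3)))
}

interface_token_mask <- function(structure, tokens, chain, cutoff) {
  cen <- token_centroids(structure, tokens)
  own <- tokens$chain == chain
  if (!any(own) || all(own)) return(own)
  other <- cen[!own, , drop = FALSE]
  near <- vapply(which(own), function(i)
    min(sqrt(rowSums(sweep(other, 2, cen[i, ])^2))) <= cutoff, logical(1))
  out <- logical(nrow(tokens))
  out[which(own)[near]] <- TRUE
  out
}

token_proximity_to_design <- function(structure, tokens, mask) {
  cen <- token_centroids(structure, tokens)
  des <- cen[mask, , drop = FALSE]
  vapply(seq_len(nrow(tokens)), function(i)
    if (mask[i]) 0 else min(sqrt(rowSums(sweep(des, 2, cen[i, ])^2))),
    numeric(1))
}

#' Crop a structure to a token budget
#'
#' Interface-biased spatial crop: a random seed token is chosen (preferring
#' interface tokens), the nearest tokens by centroid distance are kept up to
#' the budget, and within each polymer chain only contiguous runs of at
#' least 4 residues survive. Structures already within the budget are
#' returned unchanged. The folding budget defaults to 768 tokens and the
#' generative budget to 512.
#'
#' @param structure a [bk_structure()].
#' @param max_tokens token budget; defaults by `mode`.
#' @param mode `"folding"` or `"generative"`.
#' @param seed RNG seed.
#' @return cropped [bk_structure()].
#' @export
crop_structure <- function(structure, max_tokens = NULL,
                           mode = c("folding", "generative"), seed = NULL) {
  mode <- match.arg(mode)
  if (is.null(max_tokens)) max_tokens <- if (mode == "folding") 768L else 512L
  if (max_tokens < 1) stop("max_tokens must be >= 1")
  tk <- tokenize(structure)
  tokens <- tk$tokens
  if (nrow(tokens) <= max_tokens) return(structure)
  if (!is.null(seed)) { old <- .Random.seed_save(); on.exit(.Random.seed_restore(old)); set.seed(seed) }

  cen <- token_centroids(structure, tokens)
  # prefer an interface token as the crop centre
  seed_pool <- seq_len(nrow(tokens))
  if (nrow(structure$chains) > 1) {
    iface <- unlist(lapply(structure$chains$chain_id, function(ch)
      which(interface_token_mask(structure, tokens, ch, 8))))
    if (length(iface)) seed_pool <- iface
  }
  centre <- cen[sample(seed_pool, 1), ]
  keep_tok <- order(sqrt(rowSums(sweep(cen, 2, centre)^2)))[seq_len(max_tokens)]
  sel <- tokens[sort(keep_tok), , drop = FALSE]
  # contiguous runs of >= 4 residues within polymer chains
  keep_rows <- integer(0)
  a <- structure$atoms
  for (ch in unique(sel$chain)) {
    cls <- structure$chains$polymer_class[structure$chains$chain_id == ch]
    res <- sort(sel$res_index[sel$chain == ch])
    if (cls %in% c("protein", "dna", "rna")) {
      runs <- split(res, cumsum(c(1, diff(res) != 1)))
      res <- unlist(runs[vapply(runs, length, integer(1)) >= 4], use.names = FALSE)
    }
    keep_rows <- c(keep_rows, which(a$chain == ch & a$res_index %in% res))
  }
  if (!length(keep_rows)) stop("crop removed every token")
  keep_rows <- sort(keep_rows)
  remap <- match(seq_len(nrow(a)), keep_rows)
  b <- structure$bonds
  b <- b[!is.na(remap[b$a1]) & !is.na(remap[b$a2]), , drop = FALSE]
  b$a1 <- remap[b$a1]; b$a2 <- remap[b$a2]
  chains <- structure$chains[structure$chains$chain_id %in% a$chain[keep_rows], , drop = FALSE]
  bk_structure(a[keep_rows, , drop = FALSE], chains, b)
}
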