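# Brute-force N-glycan topology generator and exact Y-fragment mass counter.
# Fragments are the root-containing parts left after at most `max_cuts`
# simultaneous glycosidic cleavages (stepped-collision-energy Y ions arise
# from a small number of cleavage events per ion); distinct masses counted at
# composition level.

tree_node <- function(label, ...) list(label = label, children = list(...))

enumerate_y_compositions <- function(tree, max_cuts = 3L) {
  rec <- function(t) {
    keep <- list(list(comp = stats::setNames(1L, t$label), cuts = 0L))
    for (ch in t$children) {
      opts <- c(rec(ch),
                list(list(comp = stats::setNames(integer(0), character(0)),
                          cuts = 1L)))
      keep <- unlist(lapply(keep, function(a) lapply(opts, function(b) {
        v <- a$comp
        for (nm in names(b$comp))
          v[nm] <- ifelse(is.na(v[nm]), 0L, v[nm]) + b$comp[nm]
        list(comp = v, cuts = a$cuts + b$cuts)
      })), recursive = FALSE)
    }
    keep
  }
  lapply(Filter(function(x) x$cuts <= max_cuts, rec(tree)), `[[`, "comp")
}

count_distinct_y_masses <- function(tree, max_cuts = 3L) {
  comps <- enumerate_y_compositions(tree, max_cuts)
  masses <- vapply(comps, function(v) {
    if (!length(v)) return(0)
    sum(residue_mass(names(v)) * v)
  }, numeric(1))
  length(unique(round(masses, 4)))
}

tree_size <- function(t) 1L + sum(vapply(t$children, tree_size, integer(1)))

# canonical fixture topologies: complex/hybrid/high-mannose, n in [5, 14]
glycan_antenna <- function() tree_node("HexNAc", tree_node("Hex"))

glycan_core_tree <- function(arm1 = list(), arm2 = list(), fucosylated = FALSE) {
  man <- tree_node("Hex",
                   do.call(tree_node, c(list("Hex"), arm1)),
                   do.call(tree_node, c(list("Hex"), arm2)))
  children <- list(tree_node("HexNAc", man))
  if (fucosylated) children <- c(children, list(tree_node("dHex")))
  do.call(tree_node, c(list("HexNAc"), children))
}

topology_fixtures <- function() {
  a <- glycan_antenna
  list(
    paucimannose = list(tree = glycan_core_tree(), type = "complex"),
    paucimannose_fuc = list(tree = glycan_core_tree(fucosylated = TRUE),
                            type = "complex"),
    biantennary = list(tree = glycan_core_tree(list(a()), list(a())),
                       type = "complex"),
    biantennary_fuc = list(tree = glycan_core_tree(list(a()), list(a()), TRUE),
                           type = "complex"),
    triantennary = list(tree = glycan_core_tree(list(a(), a()), list(a())),
                        type = "complex"),
    triantennary_fuc = list(tree = glycan_core_tree(list(a(), a()), list(a()),
                                                    TRUE), type = "complex"),
    tetraantennary = list(tree = glycan_core_tree(list(a(), a()),
                                                  list(a(), a())),
                          type = "complex"),
    tetraantennary_fuc = list(tree = glycan_core_tree(list(a(), a()),
                                                      list(a(), a()), TRUE),
                              type = "complex"),
    hybrid = list(tree = glycan_core_tree(list(tree_node("Hex"),
                                               tree_node("Hex")),
                                          list(a())), type = "hybrid"),
    man5 = list(tree = glycan_core_tree(list(tree_node("Hex")),
                                        list(tree_node("Hex"))),
                type = "high-mannose"),
    man7 = list(tree = glycan_core_tree(
      list(tree_node("Hex", tree_node("Hex"))),
      list(tree_node("Hex"), tree_node("Hex"))), type = "high-mannose"),
    man9 = list(tree = glycan_core_tree(
      list(tree_node("Hex", tree_node("Hex", tree_node("Hex")))),
      list(tree_node("Hex", tree_node("Hex")),
           tree_node("Hex", tree_node("Hex")))), type = "high-mannose")
  )
}
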