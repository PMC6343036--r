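# Orchestration: run configuration, end-to-end pipeline, per-stage runners.

.defaultRunConfig <- function() {
  list(seed = 1L, alpha = 0.001, minMethods = 3L, coreMinLen = 500L,
       rdpWindowNt = 90L, maxchiWindowSites = 210L,
       chimaeraWindowSites = 60L, nPerm = 1999L, alphaP = 0.05,
       fdrQ = 0.10,
       sim = list(nStrains = 8L, genomeLength = 100000L, mu = 0.002,
                  lambda = 1, delta = 2000, nu = 0.08, w = 1))
}

#' Read a run configuration from YAML
#'
#' Unknown keys are rejected; missing keys take the documented defaults
#' (detection alpha 0.001, >=3/5 consensus, RDP window 90 nt, MaxChi 210
#' variable sites, core length 500 bp, enrichment thresholds p<0.05 and
#' FDR<10%).
#'
#' @param path Path to a YAML file (or `NULL` for pure defaults).
#' @return A named list of settings.
#' @export
readRunConfig <- function(path = NULL) {
  cfg <- .defaultRunConfig()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  bad <- setdiff(names(user), names(cfg))
  if (length(bad))
    stop("unknown config keys: ", paste(bad, collapse = ", "))
  if (!is.null(user$sim)) {
    badSim <- setdiff(names(user$sim), names(cfg$sim))
    if (length(badSim))
      stop("unknown sim config keys: ", paste(badSim, collapse = ", "))
    cfg$sim[names(user$sim)] <- user$sim
    user$sim <- NULL
  }
  cfg[names(user)] <- user
  cfg
}

.manifest <- function(cfg, outDir) {
  jsonlite::write_json(
    list(package = "coreHR",
         version = as.character(utils::packageVersion("coreHR")),
         config = cfg),
    file.path(outDir, "manifest.json"), auto_unbox = TRUE, digits = NA)
}

#' Simulate fixtures to a directory
#'
#' @param cfg Run-configuration list from [readRunConfig()].
#' @param outDir Output directory.
#' @return Invisibly, the simulation (list `block`, `truth`).
#' @export
runSimulate <- function(cfg, outDir) {
  sc <- simConfig(nStrains = cfg$sim$nStrains,
                  genomeLength = cfg$sim$genomeLength, mu = cfg$sim$mu,
                  lambda = cfg$sim$lambda, delta = cfg$sim$delta,
                  nu = cfg$sim$nu, w = cfg$sim$w, seed = cfg$seed)
  sim <- simulateAlignment(sc)
  writeFixtures(sim$block, sim$truth, outDir)
  invisible(sim)
}

#' Detect and call consensus events on an alignment
#'
#' @param block An [AlignmentBlock-class] (or path to an XMFA file, whose
#'   core blocks are extracted at `coreMinLen` and scanned one by one).
#' @param cfg Run-configuration list.
#' @param outDir Optional directory for `hits.tsv`, `events.tsv`,
#'   `summary.json`.
#' @return A list with `hits`, `events` (refined) and `summary`.
#' @export
runDetect <- function(block, cfg = readRunConfig(), outDir = NULL) {
  if (is.character(block)) {
    blocks <- extractCore(readXMFA(block), minLen = cfg$coreMinLen)
    if (!length(blocks)) stop("no core blocks of length >= ",
                              cfg$coreMinLen)
    block <- blocks[[1]]
  }
  hits <- scanAll(block,
                  settings = list(rdpWindowNt = cfg$rdpWindowNt,
                                  maxchiWindowSites = cfg$maxchiWindowSites,
                                  chimaeraWindowSites =
                                    cfg$chimaeraWindowSites,
                                  nPerm = cfg$nPerm),
                  alpha = cfg$alpha, seed = cfg$seed)
  events <- callEvents(hits, block, minMethods = cfg$minMethods,
                       alpha = cfg$alpha)
  events <- refineBreakpoints(events, block)
  summ <- summarizeSpecies(events, block)
  if (!is.null(outDir)) {
    if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
    .writeTSV(hits, file.path(outDir, "hits.tsv"), .provenance())
    .writeTSV(events, file.path(outDir, "events.tsv"), .provenance())
    jsonlite::write_json(summ, file.path(outDir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(hits = hits, events = events, summary = summ)
}

#' Compute an ANIb matrix from a directory of coords files
#'
#' Files must be named `REF__QRY.coords` (tab-delimited, show-coords
#' dialect).
#'
#' @param dir Directory of coords files.
#' @param cfg Run-configuration list.
#' @param outDir Optional output directory for `anib.tsv`.
#' @return The symmetric ANIb matrix.
#' @export
runAnib <- function(dir, cfg = readRunConfig(), outDir = NULL) {
  files <- list.files(dir, pattern = "\\.coords$", full.names = TRUE)
  if (!length(files)) stop("no .coords files in ", dir)
  base <- sub("\\.coords$", "", basename(files))
  parts <- strsplit(base, "__")
  coords <- data.frame(ref = vapply(parts, `[`, character(1), 1),
                       qry = vapply(parts, `[`, character(1), 2),
                       path = files, stringsAsFactors = FALSE)
  m <- anibMatrix(coords)
  if (!is.null(outDir)) {
    if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
    writeAnibMatrix(m, file.path(outDir, "anib.tsv"))
  }
  m
}

#' Functional enrichment of event genes
#'
#' @param events Event table (or path to an events TSV).
#' @param genes Gene table (or path to a gene TSV, see [readGeneTable()]).
#' @param cfg Run-configuration list.
#' @param outDir Optional output directory for `enrichment.tsv`.
#' @return The enrichment table from [fisherEnrichment()].
#' @export
runEnrich <- function(events, genes, cfg = readRunConfig(),
                      outDir = NULL) {
  if (is.character(events))
    events <- utils::read.delim(events, comment.char = "#",
                                stringsAsFactors = FALSE)
  if (is.character(genes)) genes <- readGeneTable(genes)
  evOG <- genesInEvents(events, genes)
  tab <- fisherEnrichment(buildCategoryTable(genes, evOG),
                          alphaP = cfg$alphaP, fdrQ = cfg$fdrQ)
  if (!is.null(outDir)) {
    if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
    .writeTSV(tab, file.path(outDir, "enrichment.tsv"), .provenance())
  }
  tab
}

#' End-to-end pipeline on a seeded simulation
#'
#' Simulates fixtures, re-reads the emitted XMFA, extracts the core,
#' scans with all five methods, calls and refines consensus events,
#' summarizes the species, estimates r/m and rho/theta, tests functional
#' enrichment against the simulated annotation, computes an ANIb matrix
#' from per-pair identities of the simulated strains, and writes a run
#' manifest. Deterministic given `cfg$seed`.
#'
#' @param cfg Run-configuration list from [readRunConfig()].
#' @param outDir Output directory.
#' @return A list with `sim`, `detect`, `recomb`, `enrich`, `anib`.
#' @export
runPipeline <- function(cfg, outDir) {
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  sim <- runSimulate(cfg, file.path(outDir, "fixtures"))
  blocks <- readXMFA(file.path(outDir, "fixtures", "alignment.xmfa"))
  core <- extractCore(blocks, minLen = cfg$coreMinLen)
  det <- runDetect(core[[1]], cfg, outDir)
  recomb <- estimateRecombParams(core[[1]], det$events)
  jsonlite::write_json(recomb, file.path(outDir, "recomb_params.json"),
                       auto_unbox = TRUE, digits = NA)
  genes <- readGeneTable(file.path(outDir, "fixtures", "genes.tsv"))
  enr <- runEnrich(det$events, genes, cfg, outDir)
  # ANIb from pairwise identities of the simulated strains (one
  # full-length fragment per ordered pair)
  M <- .blockMatrix(core[[1]])
  strains <- strainNames(core[[1]])
  pr <- utils::combn(length(strains), 2)
  rows <- lapply(seq_len(ncol(pr)), function(j) {
    i1 <- pr[1, j]; i2 <- pr[2, j]
    ok <- M[i1, ] > 0L & M[i2, ] > 0L
    idv <- 100 * (1 - sum(M[i1, ok] != M[i2, ok]) / sum(ok))
    data.frame(ref = strains[i1], qry = strains[i2],
               stringsAsFactors = FALSE,
               fragments = I(list(data.frame(ref_start = 1,
                                             ref_end = sum(ok),
                                             pct_identity = idv))))
  })
  aniM <- anibMatrix(do.call(rbind, rows))
  writeAnibMatrix(aniM, file.path(outDir, "anib.tsv"))
  .manifest(cfg, outDir)
  invisible(list(sim = sim, detect = det, recomb = recomb, enrich = enr,
                 anib = aniM))
}
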