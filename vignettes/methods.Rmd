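---
title: "Data-free RL inverse design of geometrical isomers: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Data-free RL inverse design of geometrical isomers: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psmilesRL)
```

## The problem

Given a fixed molecular scaffold — styrene, a phenyl ring conjugated to an
exocyclic C=C double bond — we want substituents for the double bond's
terminal (beta) carbon that maximize the *isomerization energy gap*: the
electronic-energy difference between the two geometrical isomers about that
bond. The search is *data-free*: no training corpus of molecules is used;
every candidate is scored on the fly by a physics-based routine, and a
reinforcement-learning agent learns the structure–reward relationship from
its own generations only.

## The P-SMILES encoding

Substituents are written in a compact SMILES-derived token grammar. The
generation alphabet has 11 symbols: the atoms `C`, `N`, `O`, `F`; the bond
symbols `E`, `Z` (a double bond in either geometry) and `#` (triple bond);
the aliphatic ring-closure digit `1`; the branch delimiters `(` and `)`;
and the two-character aromatic ring label `a1`, used in pairs like a ring
digit, which aromatizes the six-membered ring it closes. A *state* is a
sequence of at most `L` symbols, grafted textually onto the beta carbon:
the full molecule reads `Ca1C(CCCCa1)CEC` + state (the backbone's `E`/`Z`
symbol selects the isomer). For example the state `C(EC)F` is the molecule
`Ca1C(CCCCa1)CECC(EC)F`, a phenyl-bearing fluorinated diene. A state with
a leading branch, such as `(C)N`, places two substituents on the beta
carbon. The number of states of length at most L is
$\sum_{l=1}^{L} 11^l$ — 1,948,716 at L = 6 and 21,435,887 at L = 7.

Two validity notions are deliberately distinct:

* **well-formedness** (`is_well_formed`, `count_well_formed`): branches
  balanced and each ring label used an even number of times. This is the
  check a string-level converter can make before any chemistry, and it is
  the notion behind the syntactic census of a bounded space: 3,770 states
  at L = 4 and 2,430,845 at L = 7. It is exactly counted by a transfer
  matrix over (branch depth, ring-label parities).
* **grammar validity** (`is_syntactically_valid`): the state decodes to a
  legal SMILES continuation — bond symbols flanked correctly, branches
  nonempty, ring labels pairing into rings of admissible size (the
  aromatic label must close a six-membered C/N ring), no dangling bond.
  This is checked by the same parser that builds the molecular graph, so
  validity and decodability coincide by construction.

Chemical validity (valences, heteroatom rules, electron parity, 3D
behaviour) is layered on top by the reward cascade, mirroring the division
of labour between a syntax converter and a chemistry toolkit.

The decoder writes both isomer SMILES deterministically, with directional
bonds (`/`, `\`) emitted only where the geometry is chemically defined: a
reference neighbour on each side, single flanking bonds, and a beta carbon
that is neither in a ring nor cumulated. States whose two decoded isomers
coincide after canonicalization (identical substituents, ring-locked or
cumulated beta carbon) have no isomer pair and are rejected by the
cascade. Geometry annotations of substituent-internal double bonds are
emitted for plain chain patterns; in branched stereo contexts where no
reference exists the plain double bond is written. Open Babel (through
ChemmineOB) stands behind canonicalization, InChIKeys and 3D work.

## The chemical reward

`chemical_reward()` runs the validity-and-energy routine for both isomers
and returns the gap in the task's sign convention (`EZ`: E_Z − E_E;
`trans_cis`: E_cis − E_trans; `cis_trans` the negative). Stages, in
order: well-formedness; grammar decoding; isomer-pair distinctness; the
optional single-substituent constraint (invalidation only — the space of
combinations is untouched, its valid density drops); the heteroatom chain
filter (acyclic O–O or N–N bonds invalidate; ring-internal ones are
exempt); valence sanity against neutral valences (C 4, N 3, O 2, F 1);
and closed-shell parity (total electron count $\sum_i n_i Z_i$ even —
note that for valence-saturated neutral molecules the odd-valence elements
H, N, F always pair up, so this stage is a guard rather than an active
filter). Fidelity then branches:

* **toy**: a pure graph functional (below) scores each isomer directly —
  no 3D, so complete bounded spaces are scorable in seconds;
* **forcefield**: Open Babel embeds each isomer in 3D and relaxes it with
  MMFF94; a distance-based bond detector (covalent radii, cutoff factor
  1.25, a knob) re-perceives the graph, which must be isomorphic to the
  decoded one (element-labelled VF2, bond orders collapsed); MMFF94
  supplies the energies; finally the InChIKey of the relaxed structure
  must round-trip to the decoded one, catching isomerization and
  tautomerization during relaxation;
* **tight-binding** and conformer sampling are subprocess adapter
  contracts (`xtb_engine`, `crest_sampler`, the latter with a
  metadynamics-time multiplier, default 3); absent executables raise
  `EngineUnavailable` and the pipeline reports force-field-only fidelity.

Results are cached by the canonical SMILES pair of the isomers, so each
unique molecule triggers the expensive stages at most once; the unique
counts reported by the workbench use the same key.

### The toy energy functional

The toy engine makes the study conditions fully enumerable while
preserving the structure of the task. Its per-isomer pseudo-energy is

$$E = \sum_{a \in \text{syn}} \frac{w_s(a)}{1 + d_a}
    - \sum_{a \in \text{anti}} \frac{w_e(a)}{1 + d_a}
    + 0.15\, n_{\text{heavy}} + 0.4\, n_{=} - 0.25\, n_{\#},$$

where the first sum runs over the substituent syn to the aryl group
(steric strain, larger for bulkier atoms: w_s = 0.9, 0.75, 0.6, 0.45
kcal/mol for C, N, O, F), the second over the anti substituent (an
electronic stabilization increasing with electronegativity: w_e = 0.1,
0.3, 0.5, 0.8), both damped with tree depth $d_a$ from the attachment
(proximal atoms matter more), plus isomer-symmetric base terms that cancel
in gaps. The depth damping makes the functional connectivity-sensitive,
which is what gives bounded spaces a unique argmax — for the 4-token
space the optimum is the state `ONOF` with a gap of 1.425 kcal/mol over
174 unique valid molecules. These weights are fixed once; they are not
fitted to anything.

## The agent

Six transformer models share one architecture (token + learned positional
embeddings, post-norm multi-head self-attention blocks with a two-layer
feed-forward, mean pooling, linear head; Glorot-uniform initialization;
width, depth and heads are knobs with defaults 64/2/4): the master policy
(add a single token / add a paired token / stop), the single- and
double-position predictors, the single- and double-token generators, and
the value network. Generation is modification-based rather than
left-to-right: a single token is inserted at any gap of the current
string, and a paired insertion places `(`…`)` or `a1`…`a1` at two sampled
slots (the second strictly after the first), so a finished carbon chain
can be branched by one action. The masks are minimal: adds are masked at
the token budget, pair slots must enclose at least one token, and stop is
always available; all other failure modes are reward-mediated, including
the optional single-substituent constraint, which invalidates offending
generations after the fact. The networks are small and hand-backpropagated
in plain matrix algebra; the gradients are finite-difference-checked in
the test suite.

## Training

Rewards follow the shared piecewise definition: −1 for an empty (or
over-budget) termination, 0 at non-terminal steps and for invalid terminal
states, and $\alpha r_c + \beta r_d$ for valid terminal states. The
diversity reward $r_d$ is one minus the maximal Tanimoto similarity to
the trailing batch of the last $n$ valid generations (default 10);
fingerprints default to a compact in-process structural-key dictionary on
the decoded graph, with 166-bit MACCS keys through Open Babel available
as the chemistry-fidelity alternative. An empty reference batch scores
$r_d = 1$ (no reference means maximal novelty), and two empty
fingerprints count as similarity 1 (both knobs).

Both reward components are normalized by discount-based scaling: a running
accumulator $R \leftarrow \gamma R + r$ feeds a running variance, and the
raw reward is divided by the accumulator's standard deviation without mean
subtraction, one accumulator per component. The training loop floors the
standard deviation at 1 (one kcal/mol for $r_c$; the natural unit of the
[0,1]-valued $r_d$), so normalization only ever shrinks rewards: during
the first samples the running variance is still degenerate and an
unguarded division would inflate the earliest rewards by many orders of
magnitude, poisoning the value function and the top-K memory for the rest
of the run.

Optimization is PPO: clipped surrogate with one-step temporal-difference
advantages $A_t = r_t + \gamma V(s_{t+1}) - V(s_t)$ (terminal successor
value 0), squared-error value loss against $V^{target} = A_t + V(s_t)$
treated as a constant (semi-gradient), and an entropy bonus using the
base-$b$ normalized entropy with $b$ the number of currently legal
actions, so a uniform masked policy scores exactly 1 and a single legal
action contributes 0. Each policy receives gradients only from the steps
where it acted; the value network from all steps. Advantages are
recomputed with the *current* value network at every update — with
replayed trajectories this is what lets value information propagate
backwards along a trajectory over repeated updates; bootstrapping from
values stored at generation time freezes the propagation and starves the
token and position policies of credit. Replay is prioritized: the top-K
memory holds the K best unique molecules found so far, ranked by the raw
chemical reward (dedupe by canonical pair, better score kept, minimum
evicted), trajectories whose terminal state is
currently in the memory are sampled with doubled probability, and the
replay buffer pins such trajectories when trimming so the mechanism
survives buffer turnover. Optimizer is Adam (default 3e-4); batch size,
PPO passes per batch and episodes per epoch are knobs.

## Verification strategy and problem sizes

Everything quantitative in the package is anchored on exactly enumerable
spaces: closed-form combinatorics against brute enumeration; both census
dynamic programs against brute-force counting at small L; the cascade's
toy rewards against an independently written direct evaluation over the
full 3-token space; graph isomorphism against permutation search on small
graphs; the top-K memory against sort-and-truncate over all insertion
orders; PPO gradients against finite differences. The search benchmark
characterizes the 4-token toy space (174 unique valid molecules, unique
argmax) and runs three seeded trainings counting unique valid molecules
generated before the optimum first appears, against the half-of-space
random-search expectation (87 draws; the exact mean rank (n+1)/2 is
reported alongside). The benchmark configuration uses deliberately small
networks (width 8, one layer, two heads), 20 episodes per epoch, batches
of 16 trajectories with 2 PPO passes, learning rate 3e-3, entropy weight
0.1, reward weights α = β = 1 and a 700-epoch cap, a setting chosen for
reliable desk-scale convergence of this small, fully characterized task;
the scientific claim tested — fewer unique chemical-reward evaluations
than random search, on average over seeds — does not depend on these
sizes. Two implementation details proved load-bearing for that claim and
are defaults of the trainer: the top-K memory ranks molecules by the raw
chemical reward (a stationary physical ordering; ranking by the
normalized total reward lets early generations hold the memory with
inflated scores and steers prioritized replay at mediocre molecules),
and advantages are recomputed with the current value network at every
update (see above).

What the toy conditions do *not* show: force-field or higher-fidelity
energetics change the reward landscape (the printed high-fidelity gaps of
several kcal/mol, the chemically-valid counts of full spaces under
quantum-chemistry pipelines, and wall-time savings are not reproducible
without the external engines; the adapters make them possible, not
tested). The toy functional is smooth in composition, which plausibly
flatters credit assignment relative to real isomerization energetics.

## Numerical choices and edge cases

* Enumeration order is lexicographic over symbol indices; ties cannot
  occur. Budgets are guarded (`BudgetError`) before materializing a space.
* The strict-grammar census DP is validated to L = 8; beyond that,
  interactions between multiple closed rings are not tracked (two rings
  need at least 10 symbols).
* The toy engine substituent sides use tree depths from the attachment
  atom; ring closures do not shorten depths.
* Embedding uses Open Babel's deterministic 3D builder; the MM stage is
  reproducible without a seed knob.
* `tanimoto` on two empty bit sets returns 1 by default (configurable);
  entropy uses the 0·log 0 = 0 convention; clip and min ties at ρ = 1
  are smooth points, and the subgradient at the clip boundary follows the
  standard implementation (zero outside the trust region on the winning
  side).
* The full-molecule P-SMILES rendering (`full_psmiles`) is reporting
  sugar; all internal identities use canonical SMILES pairs.

## Known limitations

Substituent-internal stereo in branched contexts is dropped rather than
annotated; charged species, isotopes and stereocenters beyond double-bond
geometry are out of scope; the value function is a small network trained
by semi-gradient TD(0), so credit propagation over long episodes is slow
(episodes here have at most L + 1 decisions); and the 11-symbol grammar is
scaffold-specific — reverse-encoding arbitrary SMILES into P-SMILES is
deliberately unsupported.
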