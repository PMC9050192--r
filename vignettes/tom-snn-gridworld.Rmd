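---
title: "A spiking theory-of-mind bystander in a gridworld: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A spiking theory-of-mind bystander in a gridworld: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(tomsnn)
```

# The problem

Three agents live on a 7x7 grid with a short blocking wall: a *bystander*
and two *pedestrians*. Each agent has its own goal cell and one of three
behavioural styles -- *reckless* (pursues its goal regardless of anything),
*experienced* (additionally penalised for collisions) and *cautious*
(additionally keeps its distance from walls). The wall occludes line of
sight, so an agent can hold a false belief about where the others are.
Collisions between agents are the safety risk of interest.

The bystander carries a theory-of-mind (ToM) model built from four spiking
submodules. Each step, for every visible pedestrian, it (1) reconstructs
what that pedestrian can see (*perspective taking*), (2) infers its
behavioural style from how it has been moving (*policy inference*),
(3) predicts its next action (*action prediction*), (4) derives the
pedestrian's hypothesised next configuration and judges it safe or unsafe
(*state evaluation*). If some pedestrian is judged unsafe the bystander
stops it for one step, at a cost to its own performance score.

Everything is scored with

$$P = \max(R_{base} - C_{time}\,t - L_{collision}[collided]
      - L_{help}[helped],\ 0)$$

with $R_{base} = 50$, $C_{time} = 3$ per step, $L_{collision} = 40$ for an
agent-agent collision, and $L_{help} = 10$ charged once to the bystander if
it intervened during the episode.

# Neurons, windows and readout

All networks are two-layer feed-forward spiking networks. Input-layer
neurons are forced spike sources: an active binary channel fires on every
step of a decision window. Output neurons are leaky integrate-and-fire
(LIF) units,

$$\tau_m \frac{dV}{dt} = -(V - V_{rest}) + R\,I(t),$$

with $V_{th} = -55$ mV, $V_{rest} = -75$ mV, $\tau_m = 20$ ms, $R = 1$
(dimensionless current units) and $dt = 1$ ms. Each step integrates the
exact exponential solution of the linear membrane equation (not an Euler
step): the forward-Euler discretisation drifts more than one step from the
analytic inter-spike interval for near-threshold currents, while the exact
update reproduces the first-passage time to within one $dt$ for every
suprathreshold current, which is also what the test suite asserts.
Threshold crossings emit a spike and hard-reset the membrane to rest; there
is no refractory period.

A decision is made over a window of $T$ steps (the network constructor
default is $T = 50$; every network in the evaluated pipeline is built with
$T = 20$, see *Problem sizes* below). Output neurons are grouped into
populations of $J = 6$ with one semantic label each; the per-population
spike counts, after subtractive lateral inhibition
($c_p' = \max(0, c_p - k\sum_{q \ne p} c_q)$, $k = 0.1$), are decoded by
winner-take-all. When no population distinguishes itself (all counts
exactly equal -- a silent or untrained network), the decoder returns a
no-output sentinel and the caller falls back to its documented default
(previous estimate, "stay", or "safe").

Two readout details matter numerically. First, each neuron receives a fixed
background bias current; the six neurons of a population get evenly spaced
levels over 25-65. The spread dithers the spike-count quantisation so that
population counts become a faithful monotone readout of synaptic drive, and
the offset keeps negatively driven populations responsive instead of
rectifying them all to zero counts (which would make every such comparison
a tie). Second, the input gain (default 20) places typical learned drives
in the monotone part of the count response, below the hard ceiling of
$J \cdot T$ spikes.

# Population coding

An observation is encoded over $7 \cdot 7 \cdot (4+8) = 588$ binary
channels, twelve per cell. The layout (shipped machine-readable in
`inst/extdata/channel_layout.json`) mixes absolute and relative position
code, on the principle that the code covers both absolute and relative
positions:

* absolute channels: wall cells, the observer's own goal, occluded cells
  (cells hidden from the observer -- coding the deviation from the default
  fully visible world keeps the stimulus sparse, around 6-20 active
  channels), the observer's own cell, and up to five other agents' cells;
* relative (egocentric) channels: the goal bearing -- the first-step
  direction of a shortest path to the goal under the globally known walls
  -- a small window of wall/boundary cells around the observer, and the
  first two other agents' offsets from the observer.

Route planning is deliberately part of perception: walls and the goal are
globally known by construction, so the bearing is a deterministic function
of information the agent already has. The design question it settles is
representational: a single linear spiking readout of purely absolute
cell-wise features cannot express shortest-path detours around obstacles
(we measured a supervised ceiling of about 94% of states, which leaves a
deterministic policy stranded in roughly a third of episodes), whereas the
decision-relevant trade-offs this model actually studies -- when to deviate
from the direct path to avoid an agent or a wall -- are carried by the
relative channels and remain entirely learned.

Styles are encoded as three populations of six channels; actions as five
populations (up, down, left, right, stay) of six neurons.

For safety evaluation a *hypothesised next configuration* is encoded in
agent-centred coordinates: the 7x7 channel grid covers offsets -3..+3
around the focal pedestrian's predicted cell. Walls and the grid boundary
are wall-coded, a blocked move raises a marker at the centre, the other
agents appear at their predicted offsets, and -- separately -- at their
current offsets. The current-position channels matter because the dominant
collision mode between deterministic path-followers is the head-on *swap*,
which is invisible in a snapshot of predicted positions alone: after an
exchange neither agent sits on the other's cell. With both position sets
and the focal agent's origin encoded, same-cell, blocked-move and swap
geometry are all linearly separable.

# Plasticity

The STDP window is

$$STDP(\Delta t) = \begin{cases}
  A_+ e^{\Delta t/\tau_+} & \Delta t < 0\\
  -A_- e^{-\Delta t/\tau_-} & \Delta t > 0
\end{cases}$$

with $A_+ = 0.925$, $A_- = 0.1$, $\tau_+ = \tau_- = 20$ ms, and zero by
convention at exact coincidence. Eligibility traces follow
$\dot e = -e/\tau_e + STDP(\Delta t)\,\delta(t - t_{pre/post})$ with
$\tau_e = 5$ ms; spike pairing is nearest-neighbour against the most recent
strictly earlier opposite-side spike. Reward conversion is the discrete
rule $w \leftarrow \mathrm{clip}(w + \eta\, e\, r, -1, 1)$ with
$\eta = 0.1$, applied once per decision window; weights live in $[-1, 1]$
throughout.

## Training the decision module

The paper-level description -- "the decision module is trained by R-STDP"
-- leaves the credit-assignment scheme open, and the scheme is where
essentially all of the engineering lives. The package's rule, each
decision window:

1. **Winner-take-all eligibility.** Only the population of the *executed*
   action carries the window's eligibility trace (lateral inhibition
   suppresses the competitors' traces). The trace is normalised to a
   standard stimulation magnitude; without the normalisation an already
   dominant assembly updates an order of magnitude faster than an explored
   competitor and entrenches itself regardless of reward. A silent
   executed assembly (possible under epsilon-greedy exploration) receives
   the stimulation trace outright.
2. **Dopamine as prediction error.** The modulating signal is
   $\delta = \mathrm{clip}(r - \bar r, -1, 1)$ where $\bar r$ is a running
   reward expectation; large penalties saturate instead of destabilising
   it.
3. **Competitive transfer.** Competing populations receive the
   opposite-signed update weighted by their share of the window's
   activity.
4. **Eligibility-gated decay.** Eligible synapses relax toward zero at
   rate $\lambda = 0.15$ per update, so channels that are frequently
   active but carry no consistent reward correlation revert instead of
   accumulating a random walk.
5. **Annealing.** The learning rate decays exponentially to 1% over the
   later part of each stage, freezing the solution.

Training is staged. Stage 1 (60% of the episodes): the learner is alone in
wall-free worlds and acquires goal pursuit with the full rule above and
epsilon-greedy exploration (linear decay 1.0 to 0.05). Stage 2: worlds
gain a wall segment and one scripted reckless companion, and the style's
penalties and wall terms shape avoidance on top of the established
navigation; only the executed population is updated, at a reduced annealed
rate, so penalties depress the specific action-context associations that
caused them while ordinary progress maintains the navigation weights.

The staging is load-bearing. Under the experienced and cautious reward
functions a randomly initialised policy is punished on a large fraction of
steps, and "never move" is then genuinely the best action relative to an
adaptive expectation: un-staged training reproducibly collapses into a
frozen, never-moving policy (we observed this under several baseline and
update variants before adopting the curriculum).

## Training the ToM modules

Policy inference and action prediction receive their graded rewards
($e_{bs} = -\gamma[\hat{bs} \ne bs] + \beta$ with $\gamma = 2, \beta = 1$,
i.e. $\pm 1$; $e_{action} = \pm 1$), and state evaluation a teacher signal
from the collision predicate. All three learn with a mistake-driven,
teacher-corrected rule: nothing changes while the expressed judgment
matches the outcome by a comfortable activity margin (five spikes);
otherwise the wrongly expressed (or too-narrowly winning) population is
depressed through its own gated trace and the true population receives the
corrective stimulation trace. The rule is the dopamine-as-surprise reading
of reward modulation, it self-limits (no learning-rate schedule needed),
and it is robust to the heavy class imbalance of safety labels, where a
plain per-step reward lets the "safe" majority bury the unsafe class.

Three structural choices:

* The policy-inference recurrence (the six channels carrying the previous
  style estimate) uses fixed diagonal persistence weights (0.25),
  re-pinned after every plastic update, like the fixed perspective gating.
  A trained recurrence was unstable under error-driven updates. During
  training the expressed style is epsilon-greedy (0.3) over the three
  labels so the grading visits every class.
* The state-evaluation teacher is the collision predicate of the
  hypothesised state (blocked move, shared cell, or swap), which is
  deterministic in the encoded input; grading against the stochastic
  outcome of simultaneous moves injects irreducible label noise. During
  training the observer sweeps all five candidate actions of the observed
  pedestrian and grades each hypothesised state -- mental simulation of
  alternatives -- which supplies the rare collision geometries that
  executed behaviour alone undersamples.
* The observing bystander pursues its own goal during ToM training rather
  than watching statically, so pedestrians are observed at the interaction
  density they will have during evaluation. With a static observer, the
  action-prediction module faces out-of-distribution observations exactly
  at the multi-agent moments that matter.

The perspective-taking stage has no trainable weights at all: it is a
fixed gate that passes the agents the observer knows about through the
observed pedestrian's visibility mask (self-perspective inhibition), with
walls and goals globally known.

# The environment generator

`generate_environment()` defines the study conditions: a 7x7 grid, one
straight wall segment of 2-4 cells placed uniformly, and agents with
pairwise distinct uniformly drawn starts and goals, all disjoint from the
walls, redrawn until every goal is reachable (breadth-first search).
Visibility uses centre-to-centre ray casting: a cell is visible iff the
open segment between cell centres crosses no wall cell interior
(a corner graze does not block; the rule is symmetric).

Movement is simultaneous. Only walls and the boundary physically block; a
blocked move leaves the agent in place. Two agents ending on the same cell,
or exchanging cells, are both flagged as *colliding* but pass through --
the collision is the scored risk event, not a physical barrier. This
matters doubly: deterministic agents would otherwise deadlock against each
other forever, and the score's $L_{collision}$ is charged for collisions
*with other agents*, while the reward functions of the experienced and
cautious styles also count wall and boundary bumps. Agents that reach
their goal leave the grid. Episodes end when all agents are done or after
a step cap of 30; unfinished agents are scored with $t$ equal to the cap.

The cautious reward deserves a note: its printed form is typographically
corrupted in the source material. The package reads it as progress plus a
wall-distance term $(Dw_t - Dw_{t-1})/Dw_{t-1}$ that becomes active when
the step started within one cell of a wall, with $-5$ on any collision.
The alternative reading -- a flat $-5$ whenever the agent is near a wall,
regardless of its action -- carries no action information, which a
one-step learner cannot use at all; the adopted reading matches the stated
intent that the agent tends to move away from walls.

What the generator does *not* emulate: real pedestrian kinematics,
stochastic transitions, more than three agents, multiple or non-convex
wall structures, and goals or occlusion that change within an episode.
Passing tests therefore certify the mechanism under these idealised
conditions, not performance on anything resembling real crowds.

# Problem sizes and runtimes

The evaluated pipeline uses $T = 20$ steps per decision window, 900
episodes per style policy, 300 ToM episodes, and 100 randomized evaluation
episodes per condition; on one CPU the whole pipeline (train three
policies, train ToM, evaluate three conditions) takes about three minutes.
The policy episode count is the package's own choice: 300 episodes (the
figure stated for ToM training) does not bring the navigation policy to a
stable plateau under the staged scheme, 900 does. The acceptance tests run
the full pipeline at three seeds; `scripts/acceptance.R` runs it once at
the given seed.

# Known limitations

* **Policy ceiling.** Trained policies complete roughly nine in ten solo
  episodes near-optimally; the rest wander into the step cap. The
  bystander's mean score is dominated by its own navigation time plus its
  collision and help costs, and lands well below the published bystander
  table, whose values imply essentially optimal navigation with rare
  collisions. The acceptance suite asserts the published bands faithfully
  and reports the shortfall rather than relaxing them.
* **Style inference is weak by construction.** The (6+8) policy-inference
  input compresses behaviour into eight binary cues; their measured
  single-step Bayes ceiling over the three styles is about 45% (all three
  styles mostly walk toward their goals). The temporal persistence
  recurrence is what lifts majority-vote accuracy above chance.
* **Action prediction degrades out of context.** Accuracy predicting
  another network's action is noticeably lower in dense three-agent scenes
  than on the training stream, which caps how many imminent collisions
  the safety chain can flag in time.
* **One helper, one helped.** The bystander stops at most one pedestrian
  per step (lowest id first) and charges itself the help cost once per
  episode, keeping the score accounting unambiguous.
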