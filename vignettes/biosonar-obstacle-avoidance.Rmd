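---
title: "A closed-loop model of sonar-guided obstacle avoidance in clutter"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A closed-loop model of sonar-guided obstacle avoidance in clutter}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Echolocating bats negotiate vegetation-dense habitats in which every call
returns a cascade of overlapping echoes. Under such conditions the
individual reflectors cannot be localized: the echo train is a single
extended stimulus, not a list of object positions. `echosteer` models an
agent that must avoid obstacles using only two cues that survive this
degradation:

* **d̂**, the distance to the nearest reflector, read off the arrival time
  of the first supra-threshold echo (`d̂ = c t / 2`), and
* the **interaural level difference (ILD)** of the echo-train onset — which
  ear hears the start of the cascade louder.

Three per-call controllers consume these cues:

* **Fixed Head** — gaze locked to the drive direction; the body rotates
  away from the louder ear by an amount that grows as d̂ shrinks (50° per
  call at ≤ 0.3 m down to 25° at ≥ 1.5 m), and slows from 3 m/s to 1 m/s as
  obstacles approach.
* **DLAL** (delayed linear adaptive law) — the *head* scans: it turns away
  from the louder ear by the same distance-dependent magnitude (clamped to
  ±90°), while the *body* follows the head with delay and gain,
  `Δθᵢ = k · φ_τ` with `k = 10` and `τ = 50` ms, where `φ_τ` is the
  body-relative head angle one delay earlier, linearly interpolated from
  the head history. Speed depends on the gaze angle (3 m/s looking
  straight ahead, 1 m/s at |φ| ≥ 45°): a large gaze angle heralds a sharp
  turn.
* **Random Walk** — the collision baseline: fixed 2 m/s, per-call turns
  drawn uniformly from ±[25°, 50°].

Each control cycle is one 50 ms interpulse interval (IPI). The agent is a
unicycle of radius 16.5 cm taking one discrete step per call.

## The sensing chain

Scenes are ensembles of point scatterers. A call is a 40 kHz tone burst
(1.5 ms, raised-cosine envelope) radiated through a circular-piston beam
(10 mm aperture). Each scatterer within the frontal hemisphere of the gaze
returns the burst delayed by `2r/c`, scaled by its strength, the piston
gain, an azimuth-dependent ear gain, two-way spherical spreading `r⁻²`,
and round-trip atmospheric absorption (1.3 dB/m at 40 kHz). Ear gains are
mirrored Gaussians peaking at ±25° with σ = 40°, a parametric
approximation to a bat-like HRTF measured only as a plot; both parameters
are configuration. Both ears sit at the robot center: the model carries
level differences only, no time differences, because the controllers use
only relative loudness.

Each channel then passes a single-channel cochlear model: 4th-order
gammatone at 40 kHz (equivalent-rectangular-bandwidth width, the standard
auditory formulation — the source model is cited without a printed
bandwidth), half-wave rectification, power-law compression with exponent
0.4, and a causal 2nd-order Butterworth low-pass at 1 kHz (forward-only,
as a real-time system would run it). The known cochlear envelope of the
direct emission is subtracted and the residual clipped at zero, leaving
echoes only. The earliest local maximum exceeding a threshold in either
ear dates the first echo; both envelopes are integrated over the same
300-sample (1 ms) window starting 150 samples before that peak, giving the
onset energies whose comparison steers the robot.

The detection threshold is not printed in any source; it defaults to 10×
the RMS of the cochlear output on a pure-noise calibration call at the
configured receiver noise level, recomputed per noise setting and fixed
thereafter.

## The environments

* **Arena**: 3 × 4 m, walled, with 11 poles (collision radius 2 cm) —
  about one per square meter, placed by rejection sampling with center
  spacing ≥ 0.4 m (poles must not physically overlap) and every pole's
  nearest neighbour < 1 m. Each pole carries 20 scatterers uniform in a
  10 cm "ivy" disc with log-normal strengths (sdlog 0.5, base 0.25), so a
  single pole returns an overlapping mini-cascade.
* **Corridor**: 0.9 × 3 m, two walls lined with an "egg-carton" strip: a
  scatterer every 3 cm along the wall, displaced up to 4 cm into the
  corridor, log-normal strengths (base 0.15). Arena walls use the same
  strip model.

Base strengths and the receiver noise floor (rms 1e-4 relative to unit
source level) are modeling choices — no source publishes the reflectivity
statistics of ivy or egg cartons. They were fixed once so that a pole or
wall at the 0.3–1.5 m working range of the steering laws is reliably
detectable, as it was for the physical system the model emulates, and are
exposed as configuration.

## Closed loop, collisions, termination

Per call: synthesize → cochlear → subtract emission → detect → strategy →
kinematic step. Collisions are checked at the midpoint and endpoint of
every step (a step is at most 15 cm, so this rules out tunneling through
4 cm poles). In the arena a collision is recorded and the robot is turned
to face straight away from the contacted surface, nudged to contact
distance + 1 cm, and the trial resumes — a deterministic analogue of the
experimenter lifting the robot free; the displacement was not recorded in
the source protocol, so 1 cm is a documented convention. The intervention
also re-centers the head and clears the delayed law's head history:
physically re-aiming the robot restarts the sensorimotor loop. Without
this, a gaze-scanning agent whose head has saturated against its ±90°
clamp can re-enter the obstacle it was just lifted from on every
subsequent call — a deterministic trap with no physical counterpart
(hundreds of "collisions" per trial against the same wall). Corridor trials
end at the goal line, on first contact, or when the robot has headed
backward with decreasing axial position for 10 consecutive calls
("turned around").

All randomness in a trial — receiver noise, exact-ILD-tie coin flips,
random-walk draws, the initial pose — derives from one trial seed through
independent named streams, so trials are bit-reproducible and adding draws
to one consumer does not perturb the others.

## Design choices where the sources were open

* **Units of the delayed-law gain.** The delayed law is printed as
  `Δθᵢ = k·φ_τ` with k = 10 and τ = 50 ms. Read literally, k is a
  per-call gain in degrees per degree; read against the behavioral
  literature the law descends from, k is a turning-rate gain in s⁻¹
  (giving `Δθᵢ = k·φ_τ·IPI` per call). The package implements both
  (`gain_units` in `dlal_params()`) and defaults to the rate reading,
  which won on closed-loop evidence: it keeps commanded body rotations in
  a physically meaningful range (at most 45° per call with the ±90° head
  clamp), and in the corridor it reproduces the gaze-scanning condition's
  characteristic failure profile — a minority of completions, the rest
  lost to turning around and wall contact — where the literal reading
  drives every trial to failure. Under the literal reading a head pinned
  at its ±90° clamp commands `10 × 90 = 900°` per call, i.e. a U-turn
  every cycle, which can lock the agent into colliding with the same wall
  indefinitely; no physical platform can execute 18,000°/s. An optional
  clamp limits the per-call rotation to what the g-force bound
  `Ω = G·9.81/v` allows (off by default: the sources apply that bound only
  as a post-hoc feasibility check on the fixed-head law, and under the
  literal gain it makes the follower circle at the clamp limit instead of
  scanning).
* **What the replica does not reproduce.** With either gain reading, gaze
  scanning in the *open arena* is nearly as safe as the fixed head here:
  the simulated agent turns instantaneously and senses cleanly, so
  looking away costs it little among sparse poles. The sources' physical
  system paid a much larger arena penalty for scanning. The corridor —
  where looking sideways is immediately punished — does discriminate the
  two strategies in the replica, in the same direction and magnitude as
  the original experiments.
* **No-detection calls.** If no peak crosses threshold, the controllers
  read d̂ = d_far and keep the previous call's turn direction — flight
  toward open space. (With the default noise floor this is rare in either
  environment.)
* **Exact ILD ties** draw a fair sign from the trial's seeded stream.
* **DLAL speed law.** The speed of the gaze-scanning condition follows the
  gaze angle only, per the model description; the alternative
  distance-based reading of one figure caption is not used.
* **Walls are scatterer strips only** — no specular image-source model.
  This is the premise of the clutter-field setting: surfaces return
  distributed cascades, not mirror reflections.
* **Emission in the recording.** The exported synthesis defaults to
  echoes + noise only; the simulator adds a small direct-path copy of the
  emission (gain 0.05) and subtracts its known cochlear envelope, so the
  emission-removal stage of the pipeline operates on every call as in the
  modeled receiver.

## Numerical choices

* Speed of sound 343 m/s; sample rate 300 kHz; range cap 6 m (the 36.5 ms
  recording window fits inside the 50 ms IPI).
* Fractional echo delays are linearly interpolated between adjacent
  samples; synthesis and the gammatone stage run as FFT convolutions with
  cached kernels.
* The gammatone FIR kernel is truncated where its envelope falls below
  1e-7 of peak and normalized to unit gain at 40 kHz.
* Envelope peaks are strict local maxima; plateau ties resolve to the
  earlier sample.
* Ranging carries a systematic +0.19 m bias (envelope rise time plus
  filter group delay); the first-peak convention inherits it from the
  modeled receiver, and it stays within the half-pulse-length tolerance
  (0.26 m) that bounds end-to-end ranging error.

## What the tests do and do not show

The generator emulates the *statistics* of cluttered scenes — many
overlapping echoes per call with jittered amplitudes — not the physics of
any particular material: no multipath, no second-order scattering, no
Doppler, no frequency-dependent reflector responses, no elevation. Passing
tests therefore show that the steering laws work under dense,
non-localizable clutter as modeled, not that the simulation reproduces any
physical robot's absolute trajectory statistics (its medians depend on
hardware rate limits the model does not include, and are deliberately not
asserted).

Problem sizes used by the test suite and the acceptance script are the
study design itself: 10 trials × 600 calls (30 s of simulated flight) per
strategy in the arena, and 20 trials per strategy in the corridor with a
400-call cap. Collision-rate comparisons pool totals across trials.

## Known limitations

* Collision recovery teleports heading and position slightly; a real robot
  is turned by hand.
* The ear model is azimuthal only and Gaussian; real pinnae have
  frequency- and elevation-dependent structure.
* The per-call unicycle step has no actuator dynamics, so commanded
  rotations are executed instantaneously; realized body-rotation-rate
  distributions are therefore not comparable to a physical platform's.
  One visible consequence: the fixed head's constant ±25–50° zigzag is
  not smoothed, so its pooled body-axis-angle spread in the corridor is
  about as large as the gaze-scanner's even though its paths complete far
  more reliably.
* One cochlear channel: no spectral cues, by design.
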