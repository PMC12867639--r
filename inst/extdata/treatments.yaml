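# Treatment registry: endowments, productivities, and reward parameters for
# every supported treatment. Values with source "printed" are the published
# design parameters; values with source "reconstructed" are the asymmetric
# productivity splits, which are fixed here by the design constraints the
# treatments must satisfy (mean productivity 1.6, social dilemma 1 < p_i < 2
# for every player in two-player linear games, and full cooperation
# sustainable as a repeated-game equilibrium under aligned but not under
# misaligned inequality). Four-player treatments duplicate each two-player
# role. Thresholds follow theta = sum(p_i * e_i) / 2 and r = 20 throughout.
#
# A value written as "FIG1" is an unresolved placeholder: make_treatment()
# refuses to build the treatment and names the missing parameter.
treatments:
  - {game_type: linear, scenario: FE, n_players: 2, e: [24, 24], p: [1.6, 1.6], source: printed}
  - {game_type: linear, scenario: EI, n_players: 2, e: [36, 12], p: [1.6, 1.6], source: printed}
  - {game_type: linear, scenario: PI, n_players: 2, e: [24, 24], p: [1.9, 1.3], source: reconstructed}
  - {game_type: linear, scenario: AI, n_players: 2, e: [36, 12], p: [1.9, 1.3], source: reconstructed}
  - {game_type: linear, scenario: MI, n_players: 2, e: [36, 12], p: [1.3, 1.9], source: reconstructed}
  - {game_type: threshold, scenario: FE, n_players: 2, e: [24, 24], p: [1.6, 1.6], theta: 38.4, r: 20, source: printed}
  - {game_type: threshold, scenario: EI, n_players: 2, e: [36, 12], p: [1.6, 1.6], theta: 38.4, r: 20, source: printed}
  - {game_type: threshold, scenario: PI, n_players: 2, e: [24, 24], p: [1.9, 1.3], theta: 38.4, r: 20, source: reconstructed}
  - {game_type: threshold, scenario: AI, n_players: 2, e: [36, 12], p: [1.9, 1.3], theta: 42.0, r: 20, source: reconstructed}
  - {game_type: threshold, scenario: MI, n_players: 2, e: [36, 12], p: [1.3, 1.9], theta: 34.8, r: 20, source: reconstructed}
  - {game_type: linear, scenario: FE, n_players: 4, e: [24, 24, 24, 24], p: [1.6, 1.6, 1.6, 1.6], source: printed}
  - {game_type: linear, scenario: AI, n_players: 4, e: [36, 36, 12, 12], p: [1.9, 1.9, 1.3, 1.3], source: reconstructed}
  - {game_type: linear, scenario: MI, n_players: 4, e: [36, 36, 12, 12], p: [1.3, 1.3, 1.9, 1.9], source: reconstructed}
  - {game_type: threshold, scenario: FE, n_players: 4, e: [24, 24, 24, 24], p: [1.6, 1.6, 1.6, 1.6], theta: 76.8, r: 20, source: printed}
  - {game_type: threshold, scenario: AI, n_players: 4, e: [36, 36, 12, 12], p: [1.9, 1.9, 1.3, 1.3], theta: 84.0, r: 20, source: reconstructed}
  - {game_type: threshold, scenario: MI, n_players: 4, e: [36, 36, 12, 12], p: [1.3, 1.3, 1.9, 1.9], theta: 69.6, r: 20, source: reconstructed}
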