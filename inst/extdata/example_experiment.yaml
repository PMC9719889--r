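# Example experiment: 8 parallel reactors, intermittent exponential feeding
# plus one-sided pH control, 2 h simulated horizon.
experiment:
  name: example
  operator: demo
reactors:
  count: 8
  glucose: 1.0
  pH: 7.0
  fill_mL: 10
lhs_profile:
  n_channels: 8
  channel_volume_min: 5
  per_cycle_duration: 30
  per_method_overhead:
    feed: 30
    ph_control: 30
clock:
  tick: 10
  duration: 7200
  mode: event_driven
  acquisition_interval: 60
plant:
  malfunction_rate: 0
seed: 1
tasks:
  - name: feed
    task_class: feeding
    source: substrate
    priority: {p_base: 10, p_crit: 100, algorithm: dynamic_time}
    demand:
      kind: exponential_feed
      plant_effect: feed
      parameters: {base_volume: 60, mu_set: 0.2}
    constraints:
      - {name: min_feed_interval, kind: hard, quantity: elapsed_time, bound: lower, limit: 1500}
      - {name: max_feed_interval, kind: soft, quantity: elapsed_time, bound: upper, limit: 2100}
      - {name: min_pipettable, kind: hard, quantity: volume, bound: lower, limit: 5}
      - {name: max_channel_volume, kind: hard, quantity: volume, bound: upper, limit: 1000}
      - {name: working_volume_cap, kind: hard, quantity: fill_level, bound: upper, limit: 15000}
  - name: ph_control
    task_class: ph_control
    source: base
    priority: {p_base: 10, p_crit: 80, algorithm: dynamic_volume}
    demand:
      kind: proportional_titration
      plant_effect: base
      parameters: {gain: 60, setpoint: 7.0, deadband: 0.1}
    constraints:
      - {name: min_pipettable, kind: hard, quantity: volume, bound: lower, limit: 5}
      - {name: base_volume_ceiling, kind: soft, quantity: volume, bound: upper, limit: 60}
      - {name: working_volume_cap, kind: hard, quantity: fill_level, bound: upper, limit: 15000}
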