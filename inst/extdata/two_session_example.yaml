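# Two sessions of two 1-moment presentations at a 32-moment ISI with the
# standard stimulus and context parameters: short-term habituation within each
# session, context-driven long-term habituation across sessions.
schema_version: 1
nodes:
  ctx: {p1: 0.05, pd1: 0.1, pd2: 0.02, role: context}
  s: {p1: 0.8, pd1: 0.1, pd2: 0.02, role: explicit}
modulation: {theta: 0.07, c1: 2, c2: 10}
learning: {L_plus: 0.02, L_minus: 0.0004}
response: {w1: 1, w2: 0, f: identity}
sessions:
  - length: 300
    context_on: true
    events:
      - {node: s, onset: 60, duration: 1}
      - {node: s, onset: 92, duration: 1}
  - length: 300
    context_on: true
    events:
      - {node: s, onset: 60, duration: 1}
      - {node: s, onset: 92, duration: 1}
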