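# Reference synthetic corpus: 5 topics, 12 documents per topic, planted
# words at topic spreads 1-5 with equal expected total frequency (24
# insertions each), one topic-keyed ambiguous word and one spread-matched
# ambiguous word. Pipeline block holds the run settings used with it.
n_topics: 5
docs_per_topic: 12
doc_length: 240
vocab_per_topic: 60
shared_vocab: 40
shared_fraction: 0.3
seed: 42
planted:
  - {word: narrowa,     topics: [1],           rate: 2.0}
  - {word: narrowb,     topics: [2],           rate: 2.0}
  - {word: spantwoa,    topics: [1, 2],        rate: 1.0}
  - {word: spantwob,    topics: [3, 4],        rate: 1.0}
  - {word: spanthreea,  topics: [1, 3, 5],     rate: 0.6667}
  - {word: spanthreeb,  topics: [2, 4, 5],     rate: 0.6667}
  - {word: spanfoura,   topics: [1, 2, 3, 4],  rate: 0.5}
  - {word: spanfourb,   topics: [2, 3, 4, 5],  rate: 0.5}
  - {word: spanfivea,   topics: [1, 2, 3, 4, 5], rate: 0.4}
  - {word: spanfiveb,   topics: [1, 2, 3, 4, 5], rate: 0.4}
  - word: twokeyed          # meanings keyed to disjoint topics
    topics: [1, 4]
    rate: 1.0
    meanings: {"1": meadow, "4": finance}
  - word: evenblend         # meanings share an identical topic profile
    topics: [1, 2, 3, 4, 5]
    rate: 0.5
    meanings: random
    meaning_labels: [sensea, senseb]
pipeline:
  window: 100
  min_count: 10
  min_contexts: 5
  k: 50
  scaled: true
  seed: 1
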