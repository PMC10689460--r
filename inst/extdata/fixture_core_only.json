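{"nodes":[{"id":1,"type":"input","act":"linear","bias":0},{"id":2,"type":"input","act":"linear","bias":0},{"id":3,"type":"input","act":"linear","bias":0},{"id":4,"type":"input","act":"linear","bias":0},{"id":5,"type":"output","act":"linear","bias":0},{"id":6,"type":"output","act":"linear","bias":0},{"id":7,"type":"output","act":"linear","bias":10},{"id":8,"type":"output","act":"linear","bias":1},{"id":9,"type":"output","act":"linear","bias":0}],"conns":[]}
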