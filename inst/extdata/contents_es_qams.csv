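sample_id,analyte,es_ug_g,qams_ug_g
SD-JL256,C,107.1,106.0
SD-JL256,U,88.9,87.0
SD-JL256,dU,4.2,4.1
SD-JL256,I,33.3,31.7
SD-JL256,G,132.4,
SD-JL256,dG,7.9,7.8
SD-JL256,dC,9.3,8.9
SD-JL256,A,40.7,39.1
SD-JL256,dA,3.1,3.5
SD-XJ266,C,129.8,126.0
SD-XJ266,U,165.3,160.3
SD-XJ266,dU,,
SD-XJ266,I,52.5,49.7
SD-XJ266,G,166.4,
SD-XJ266,dG,8.1,8.0
SD-XJ266,dC,10.4,9.7
SD-XJ266,A,63.6,62.3
SD-XJ266,dA,4.2,4.2
SD-JL243,C,152.9,152.0
SD-JL243,U,108.6,108.0
SD-JL243,dU,4.0,3.9
SD-JL243,I,36.4,34.6
SD-JL243,G,186.1,
SD-JL243,dG,9.6,9.6
SD-JL243,dC,13.1,12.8
SD-JL243,A,45.2,44.2
SD-JL243,dA,6.8,6.8
SD-XJ260,C,123.2,122.5
SD-XJ260,U,126.7,123.7
SD-XJ260,dU,,
SD-XJ260,I,34.2,32.6
SD-XJ260,G,131.2,
SD-XJ260,dG,7.4,7.3
SD-XJ260,dC,10.1,9.6
SD-XJ260,A,41.6,39.0
SD-XJ260,dA,3.9,3.5
SD-JL235,C,96.3,92.0
SD-JL235,U,91.5,79.8
SD-JL235,dU,,
SD-JL235,I,36.8,35.0
SD-JL235,G,127.5,
SD-JL235,dG,5.9,5.8
SD-JL235,dC,7.4,6.9
SD-JL235,A,44.4,42.6
SD-JL235,dA,1.3,1.3
SD-JL244,C,85.2,91.9
SD-JL244,U,93.3,90.8
SD-JL244,dU,4.0,3.9
SD-JL244,I,34.9,33.2
SD-JL244,G,104.9,
SD-JL244,dG,4.2,4.0
SD-JL244,dC,3.4,3.1
SD-JL244,A,41.9,39.3
SD-JL244,dA,,
SD-JL250,C,92.7,88.8
SD-JL250,U,101.4,98.4
SD-JL250,dU,,
SD-JL250,I,39.8,37.8
SD-JL250,G,129.1,
SD-JL250,dG,5.7,5.6
SD-JL250,dC,5.6,5.4
SD-JL250,A,48.2,46.1
SD-JL250,dA,,
SD-XJ268,C,76.0,74.2
SD-XJ268,U,122.3,120.6
SD-XJ268,dU,,
SD-XJ268,I,37.9,36.0
SD-XJ268,G,95.7,
SD-XJ268,dG,4.0,3.8
SD-XJ268,dC,1.3,1.4
SD-XJ268,A,45.6,44.7
SD-XJ268,dA,,
SD-XJ278,C,102.0,99.3
SD-XJ278,U,191.3,186.1
SD-XJ278,dU,,
SD-XJ278,I,67.7,64.0
SD-XJ278,G,141.2,
SD-XJ278,dG,5.5,5.4
SD-XJ278,dC,5.2,5.0
SD-XJ278,A,81.5,80.7
SD-XJ278,dA,,
SD-XJ287,C,75.3,73.6
SD-XJ287,U,123.9,121.3
SD-XJ287,dU,4.1,4.1
SD-XJ287,I,40.5,38.5
SD-XJ287,G,90.1,
SD-XJ287,dG,4.0,3.8
SD-XJ287,dC,1.3,1.4
SD-XJ287,A,50.0,48.7
SD-XJ287,dA,,
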