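cohort,status,percent,kb,ru
15,manifesting,15.2,28,8
15,nonmanifesting,25.4,28,8
28,manifesting,14.6,29,8
28,nonmanifesting,25.2,29,8
29,manifesting,6.5,30,8.5
29,nonmanifesting,12.5,30,8.5
30,manifesting,10.6,30,8.5
30,nonmanifesting,32.6,30,8.5
43,manifesting,14.2,19,5
43,nonmanifesting,15.5,19,5
46,manifesting,13.7,22,6
46,nonmanifesting,27.6,22,6
47,manifesting,9.3,30,8.5
47,nonmanifesting,14.9,30,8.5
47,nonmanifesting,16.9,30,8.5
48,manifesting,7.3,21,6
48,manifesting,4.9,21,6
48,nonmanifesting,11.7,21,6
49,manifesting,8.0,22,6
49,nonmanifesting,18.8,22,6
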