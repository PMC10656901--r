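"cluster_id","component"
0,"mainly bird"
1,"mainly bird"
2,"mainly bird"
3,"mainly bird"
4,"mainly bird"
5,"mainly bird"
6,"mainly bird"
7,"mainly bird"
8,"mainly bird"
9,"mainly bird"
10,"mainly bird"
11,"mainly bird"
12,"mainly bird"
13,"mainly bird"
14,"mainly insect"
15,"mainly insect"
16,"mainly insect"
17,"mainly insect"
18,"mainly insect"
19,"mainly insect"
20,"mainly insect"
21,"mainly insect"
22,"mainly insect"
23,"mainly insect"
24,"mainly insect"
25,"mainly insect"
26,"mainly insect"
27,"mainly insect"
28,"mainly insect"
29,"mainly insect"
30,"mainly insect"
31,"mainly insect"
32,"mainly insect"
33,"mainly insect"
34,"mainly insect"
35,"mainly insect"
36,"mainly insect"
37,"mainly insect"
38,"mainly insect"
39,"mainly insect"
40,"mainly insect"
41,"mainly insect"
42,"mainly insect"
43,"mainly insect"
44,"mainly rain"
45,"mainly rain"
46,"mainly rain"
47,"mainly rain"
48,"mainly rain"
49,"mainly rain"
50,"mainly rain"
51,"mainly rain"
52,"mainly rain"
53,"mainly rain"
54,"mainly rain"
55,"mainly rain"
56,"no obvious biophony"
57,"no obvious biophony"
58,"no obvious biophony"
59,"no obvious biophony"
60,"no obvious biophony"
61,"no obvious biophony"
62,"no obvious biophony"
63,"no obvious biophony"
64,"no obvious biophony"
65,"no obvious biophony"
66,"no obvious biophony"
67,"no obvious biophony"
68,"no obvious biophony"
69,"no obvious biophony"
70,"no obvious biophony"
71,"no obvious biophony"
72,"no obvious biophony"
73,"no obvious biophony"
74,"no obvious biophony"
75,"no obvious biophony"
76,"no obvious biophony"
77,"no obvious biophony"
78,"bird and insect"
79,"bird and insect"
80,"bird and insect"
81,"bird and insect"
82,"bird and insect"
83,"bird and insect"
84,"bird and insect"
85,"bird and insect"
86,"bird and insect"
87,"bird and insect"
88,"bird and insect"
89,"bird and insect"
90,"bird and rain"
91,"bird and rain"
92,"biophony and anthropophony"
93,"biophony and anthropophony"
94,"biophony and anthropophony"
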