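fk4	lo	4.8296294321014571e-01 8.3651633380341950e-01 2.2414383797640183e-01 -1.2940955261687195e-01
fk6	lo	5.0335366352116517e-01 7.4939223616728279e-01 3.5878739728439096e-01 -1.4641928318370925e-01 -1.5503427961900867e-01 1.0413382820297404e-01
fk8	lo	4.0747792436323149e-01 7.6063663437010931e-01 4.3048715064720505e-01 -6.6214877307675307e-02 -2.2458409803930535e-01 6.2897218443095509e-02 9.3725804215416333e-02 -5.0212194318982016e-02
fk14	lo	3.5843355993637949e-01 6.9965521080425763e-01 5.2807896396968868e-01 3.8637318466377278e-03 -2.4301849172973672e-01 -4.3409445179613843e-02 1.4473277617350899e-01 3.6972784841941053e-02 -9.9181887546755929e-02 -2.2944615830263939e-02 7.4212844286000723e-02 4.2029417237118352e-03 -5.6150983902537581e-02 2.8766172979877210e-02
fk18	lo	3.2138367357017938e-01 6.7414366020134775e-01 5.6495641974859612e-01 5.7991829993646840e-02 -2.4636132822942441e-01 -8.5106619956437118e-02 1.4081825749947177e-01 7.1820227514235266e-02 -9.3677790114502932e-02 -5.5970954372462918e-02 6.9261248362443864e-02 4.1402491428859552e-02 -5.5743869637742693e-02 -2.7152214528238301e-02 4.7953003593558481e-02 1.0202293899712741e-02 -4.1482833606031971e-02 1.9776067005883802e-02
fk22	lo	2.9448056410968471e-01 6.5185173812933761e-01 5.8897707715498970e-01 1.0205112718988867e-01 -2.4234181230702825e-01 -1.1710300896554765e-01 1.3132646101222342e-01 9.6820260645571032e-02 -8.3317975378552372e-02 -7.7308465844216592e-02 5.9016004950187349e-02 6.1523390925432110e-02 -4.5722521037860113e-02 -4.8682613719833179e-02 3.8507566485934321e-02 3.7378731211955611e-02 -3.4965547981722606e-02 -2.6100587949389780e-02 3.3800377369517784e-02 1.1924696257214566e-02 -3.2653413190826382e-02 1.4751513306135229e-02
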