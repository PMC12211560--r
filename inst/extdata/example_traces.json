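{
  "format": "mitoshape-traces",
  "version": 1,
  "units": "nm",
  "traces": [
    {
      "id": "example_tubule",
      "outline": {
        "x": [250, 303.959449738409, 347.345968680947, 371.658308863133, 372.132657987434, 348.676071064815, 305.884682256065, 252.143128445503, 196.349540849362, 140.555848243192, 84.7621556370216, 28.9684630308513, -26.8252295753189, -82.6189221814892, -138.412614787659, -194.20630739383, -250, -303.959449738409, -347.345968680947, -371.658308863133, -372.132657987434, -348.676071064815, -305.884682256065, -252.143128445503, -196.349540849362, -140.555848243192, -84.7621556370217, -28.9684630308515, 26.825229575319, 82.6189221814892, 138.412614787659, 194.20630739383],
        "y": [-125, -112.753615391827, -78.4140445428496, -28.7098569234059, 26.619801894912, 76.7335193980546, 111.811905847001, 124.981626651545, 125, 125, 125, 125, 125, 125, 125, 125, 125, 112.753615391827, 78.4140445428496, 28.709856923406, -26.6198018949119, -76.7335193980547, -111.811905847001, -124.981626651545, -125, -125, -125, -125, -125, -125, -125, -125]
      },
      "cristae": [
        {
          "x": [-125, -125],
          "y": [-100, 100]
        },
        {
          "x": [0, 0],
          "y": [-100, 100]
        },
        {
          "x": [125, 125],
          "y": [-100, 100]
        }
      ],
      "group_label": "control"
    },
    {
      "id": "example_sphere",
      "outline": {
        "x": [1.22464679914735e-14, 39.0180644032257, 76.536686473018, 111.11404660392, 141.42135623731, 166.293922460509, 184.775906502257, 196.157056080646, 200, 196.157056080646, 184.775906502257, 166.293922460509, 141.42135623731, 111.11404660392, 76.5366864730179, 39.0180644032257, 1.22464679914735e-14, -39.0180644032257, -76.5366864730179, -111.11404660392, -141.421356237309, -166.293922460509, -184.775906502257, -196.157056080646, -200, -196.157056080646, -184.775906502257, -166.293922460509, -141.421356237309, -111.11404660392, -76.5366864730181, -39.0180644032257],
        "y": [-200, -196.157056080646, -184.775906502257, -166.293922460509, -141.421356237309, -111.11404660392, -76.536686473018, -39.0180644032256, 0, 39.0180644032257, 76.536686473018, 111.11404660392, 141.421356237309, 166.293922460509, 184.775906502257, 196.157056080646, 200, 196.157056080646, 184.775906502257, 166.293922460509, 141.42135623731, 111.11404660392, 76.536686473018, 39.0180644032256, 2.44929359829471e-14, -39.0180644032257, -76.536686473018, -111.11404660392, -141.42135623731, -166.293922460509, -184.775906502257, -196.157056080646]
      },
      "cristae": [],
      "group_label": "control"
    },
    {
      "id": "example_jittered",
      "outline": {
        "x": [450, 529.280254154736, 585.691502169657, 600.548743589713, 565.416683943613, 492.532283697443, 407.024311274043, 321.321880146639, 235.619449019234, 149.91701789183, 64.2145867644258, -21.4878443629784, -107.190275490383, -192.892706617787, -278.595137745191, -364.297568872596, -450, -528.993121205429, -580.335907166946, -592.358845116987, -561.996175703659, -493.153659661887, -407.024311274043, -321.321880146639, -235.619449019235, -149.91701789183, -64.2145867644258, 21.4878443629786, 107.190275490383, 192.892706617787, 278.595137745192, 364.297568872596],
        "y": [-146.302957468576, -123.321569888359, -61.918754562789, 21.7151975395873, 100.131143332549, 145.256934466021, 150.507687371287, 151.651675705045, 152.905831015177, 151.907936384341, 149.224997866714, 147.626853190095, 148.597860582254, 150.91366922488, 152.448617085746, 152.064636940894, 149.686328250993, 122.874930476658, 59.4748891238467, -20.5338840398938, -97.1636399427242, -147.379067582316, -155.872719635546, -154.566011347909, -152.457619952329, -151.860743572611, -151.98799716522, -150.972580949122, -148.981569442912, -147.712130283189, -147.542182318257, -147.179328548184]
      },
      "cristae": [
        {
          "x": [-300, -300],
          "y": [-120, 120]
        },
        {
          "x": [-150, -150],
          "y": [-120, 120]
        },
        {
          "x": [0, 0],
          "y": [-120, 120]
        },
        {
          "x": [150, 150],
          "y": [-120, 120]
        },
        {
          "x": [300, 300],
          "y": [-120, 120]
        }
      ],
      "group_label": "perturbed"
    }
  ]
}
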